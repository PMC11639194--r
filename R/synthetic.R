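#' Noise and artifact specification for synthetic traces
#'
#' @param sigma additive Gaussian noise, as a fraction of the peak absolute
#'   current of each sweep (default 0.01).
#' @param g_leak linear leak conductance (per-channel units; default 0).
#' @param E_leak leak reversal potential (mV).
#' @param cap_A capacitive transient amplitude per mV of step (default 0);
#'   the transient is bi-exponential with time constants `0.3 * cap_tau`
#'   and `cap_tau`.
#' @param cap_tau capacitive time constant (ms).
#' @param seed RNG seed; mandatory whenever `sigma > 0`.
#' @return object of class `kv_noise_spec`.
#' @export
kv_noise_spec <- function(sigma = 0.01, g_leak = 0, E_leak = 0,
                          cap_A = 0, cap_tau = 1, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma > 0 && is.null(seed)) stop("a seed is mandatory for nonzero noise")
  structure(list(sigma = sigma, g_leak = g_leak, E_leak = E_leak,
                 cap_A = cap_A, cap_tau = cap_tau, seed = seed),
            class = "kv_noise_spec")
}

#' Replicate (per-oocyte) variability specification
#'
#' Emulates the spread across oocytes seen in pooled electrophysiology
#' tables: each replicate multiplies every kinetic rate constant by an
#' independent log-normal factor with coefficient of variation `cv`.
#'
#' @param n_oocytes number of replicates (>= 1).
#' @param cv log-normal coefficient of variation of the rate multipliers
#'   (default 0.1).
#' @return object of class `kv_replicate_spec`.
#' @export
kv_replicate_spec <- function(n_oocytes = 1, cv = 0.1) {
  if (n_oocytes < 1) stop("n_oocytes must be >= 1")
  if (cv < 0) stop("cv must be >= 0")
  structure(list(n_oocytes = n_oocytes, cv = cv),
            class = "kv_replicate_spec")
}

.jitter_params <- function(params, cv) {
  if (cv == 0) return(params)
  sdlog <- sqrt(log(1 + cv^2))
  for (nm in c("a0", "b0", "ko", "kc", "kd", "ku", "kb", "kub",
               "kci", "kcr", "kci0", "kcr0")) {
    if (params[[nm]] > 0)
      params[[nm]] <- params[[nm]] * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
  }
  params
}

#' Generate a synthetic study dataset
#'
#' Simulates `reps$n_oocytes` replicates of a protocol under per-replicate
#' rate jitter, adds Gaussian noise and optional linear-leak / capacitive
#' artifacts, and (optionally) writes one CSV per replicate plus a JSON
#' truth manifest of the exact per-replicate rate constants.  Deterministic
#' for a given seed.
#'
#' @param params calibrated [kv_rate_params()] (scheme attached).
#' @param cond a [kv_condition()].
#' @param protocol a [kv_protocol()].
#' @param noise a [kv_noise_spec()].
#' @param reps a [kv_replicate_spec()].
#' @param out_dir optional output directory for CSV traces + manifest.
#' @param kind "ionic" or "gating".
#' @return invisibly, a list with `families` (one `kv_sweep_family` per
#'   replicate, artifacts applied), `truth` (per-replicate rate lists) and
#'   `manifest_path` (or NULL).
#' @export
generate_dataset <- function(params, cond, protocol,
                             noise = kv_noise_spec(sigma = 0),
                             reps = kv_replicate_spec(1, cv = 0),
                             out_dir = NULL, kind = "ionic") {
  scheme <- attr(params, "scheme") %||% kv_scheme_full()
  if (!is.null(noise$seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(noise$seed)
  }
  art <- list(g_leak = noise$g_leak, E_leak = noise$E_leak,
              cap_A = noise$cap_A, cap_tau = noise$cap_tau)
  families <- vector("list", reps$n_oocytes)
  truth <- vector("list", reps$n_oocytes)
  for (r in seq_len(reps$n_oocytes)) {
    pr <- .jitter_params(params, reps$cv)
    attr(pr, "scheme") <- scheme
    fam <- if (kind == "gating") {
      attr(pr, "nonconducting") <- TRUE
      simulate_gating(pr, cond, protocol, scheme)
    } else simulate_ionic(pr, cond, protocol, scheme)
    for (k in seq_along(fam$traces)) {
      tr <- fam$traces[[k]]
      cur <- .add_linear_artifacts(tr, art)
      if (noise$sigma > 0) {
        pk <- max(abs(cur))
        cur <- cur + stats::rnorm(length(cur), 0, noise$sigma * pk)
      }
      tr$current <- cur
      fam$traces[[k]] <- tr
    }
    attr(fam, "artifacts") <- art
    families[[r]] <- fam
    truth[[r]] <- list(replicate = r,
                       rates = unclass(pr)[c("a0", "b0", "ko", "kc", "kd",
                                             "ku", "kb", "kub", "kci", "kcr",
                                             "kci0", "kcr0")])
  }
  manifest_path <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (r in seq_len(reps$n_oocytes)) {
      write_trace_csv(families[[r]],
                      file.path(out_dir, sprintf("rep%02d.csv", r)))
    }
    manifest_path <- file.path(out_dir, "truth_manifest.json")
    jsonlite::write_json(
      list(seed = noise$seed, sigma = noise$sigma, cv = reps$cv,
           kind = kind, protocol = protocol$id,
           condition = unclass(cond), replicates = truth),
      manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(families = families, truth = truth,
                 manifest_path = manifest_path))
}

#' Curated small fixture suite
#'
#' Writes one small noiseless fixture per core analysis (a wild-type 1-s
#' decay, an I8Q two-pulse recovery family with the dense interval list, a
#' dN 10-s decay) plus one small noisy replicate ensemble per channel.
#' Regeneration with the same seed is byte-identical.
#'
#' @param out_dir output directory.
#' @param seed RNG seed for the noisy ensembles.
#' @return invisibly, the vector of written files.
#' @export
make_fixture_suite <- function(out_dir, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  nd <- kv_condition(preset = "ND96")
  jobs <- list(
    list(name = "AKv1_decay_1s", ch = "AKv1",
         proto = make_step_family(40, 40, 10, 1000)),
    list(name = "I8Q_recovery_dense", ch = "I8Q",
         proto = make_two_pulse(1000, recovery_intervals("dense"),
                                test_ms = 20)),
    list(name = "dN_decay_10s", ch = "dN",
         proto = make_step_family(40, 40, 10, 10000)))
  written <- character(0)
  for (j in jobs) {
    p <- kv_preset(j$ch)
    fam <- simulate_ionic(p, nd, j$proto)
    f <- file.path(out_dir, paste0(j$name, ".csv"))
    write_trace_csv(fam, f)
    written <- c(written, f)
  }
  for (ch in c("AKv1", "I8Q", "dN")) {
    p <- kv_preset(ch)
    proto <- make_step_family(40, 40, 10,
                              if (ch == "dN") 10000 else 1000)
    ds <- generate_dataset(p, nd, proto,
                           noise = kv_noise_spec(sigma = 0.01, seed = seed),
                           reps = kv_replicate_spec(3, cv = 0.1),
                           out_dir = file.path(out_dir, paste0(ch, "_noisy")))
    written <- c(written, ds$manifest_path)
  }
  invisible(written)
}
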