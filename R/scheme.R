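#' Channel state scheme
#'
#' A `kv_scheme` is the state graph of a Markov channel model: an ordered set
#' of state labels, the subset of states that conduct ionic current, and a
#' list of reversible transitions.  Each transition names its forward and
#' backward rate (resolved against a [kv_rate_params()] object when the
#' generator matrix is built) and the gating charge `z` (elementary charges)
#' moved in the depolarizing (forward) direction.
#'
#' @param states character vector of state labels, ordered along the
#'   activation path.
#' @param conducting subset of `states` that carry ionic current.
#' @param edges data.frame with columns `from`, `to`, `fwd`, `bwd`, `z`:
#'   one row per reversible transition (`fwd`/`bwd` are rate names, `z` the
#'   charge moved from -> to).
#' @param name optional scheme label.
#' @return object of class `kv_scheme`.
#' @seealso [kv_scheme_full()], [kv_scheme_dn()], [build_generator()]
#' @export
kv_scheme <- function(states, conducting, edges, name = "custom") {
  stopifnot(is.character(states), length(states) >= 2, !anyDuplicated(states))
  needed <- c("from", "to", "fwd", "bwd", "z")
  if (!all(needed %in% names(edges)))
    stop("edges must have columns from, to, fwd, bwd, z")
  edges <- as.data.frame(edges)[, needed]
  if (!all(conducting %in% states))
    stop("conducting states must be a subset of states")
  if (!all(c(edges$from, edges$to) %in% states))
    stop("edge endpoints must be listed states")
  if (any(edges$from == edges$to)) stop("self-transitions are not allowed")
  structure(list(states = states, conducting = conducting,
                 edges = edges, name = name),
            class = "kv_scheme")
}

#' @export
print.kv_scheme <- function(x, ...) {
  cat("<kv_scheme '", x$name, "'> ", length(x$states), " states: ",
      paste(x$states, collapse = " "), "\n", sep = "")
  cat("  conducting:", paste(x$conducting, collapse = " "), "\n")
  cat("  ", nrow(x$edges), " reversible transitions, total forward charge ",
      sum(x$edges$z), " e0\n", sep = "")
  invisible(x)
}

#' Full Kv1 scheme with N-type and C-type inactivation
#'
#' Nine states: a four-step activation path `C0..C3 -> O`, a conducting
#' pre-block state `P` (amino terminus docked at the T1 window, pore still
#' open), the pore-blocked N-type inactivated state `N`, the doubly
#' inactivated state `NC` (N-type block plus C-type collapse of the outer
#' pore), and a direct C-type state `Cf` reached from the open state (used by
#' amino-terminal deletion constructs; its entry rate `kci0` is zero in
#' wild-type-like presets).
#'
#' The three `C-C` sensor steps each move 3 e0; the concerted opening step
#' moves 4 e0 (total 13 e0).  Dock/undock (`kd`/`ku`), block/unblock
#' (`kb`/`kub`) and C-type transitions carry no gating charge.
#'
#' @return a [kv_scheme()].
#' @export
kv_scheme_full <- function() {
  kv_scheme(
    states = c("C0", "C1", "C2", "C3", "O", "P", "N", "NC", "Cf"),
    conducting = c("O", "P"),
    edges = data.frame(
      from = c("C0", "C1", "C2", "C3", "O",  "P",  "N",   "O"),
      to   = c("C1", "C2", "C3", "O",  "P",  "N",  "NC",  "Cf"),
      fwd  = c("a",  "a",  "a",  "ko", "kd", "kb", "kci", "kci0"),
      bwd  = c("b",  "b",  "b",  "kc", "ku", "kub", "kcr", "kcr0"),
      z    = c(3, 3, 3, 4, 0, 0, 0, 0)),
    name = "Kv1-NC")
}

#' Amino-terminal deletion scheme (C-type only)
#'
#' Same activation path as [kv_scheme_full()] but without the pre-block,
#' N-inactivated and N-C states: the only inactivation is the direct
#' open-to-C-type step `O <-> Cf` (`kci0`/`kcr0`).
#'
#' @return a [kv_scheme()].
#' @export
kv_scheme_dn <- function() {
  kv_scheme(
    states = c("C0", "C1", "C2", "C3", "O", "Cf"),
    conducting = "O",
    edges = data.frame(
      from = c("C0", "C1", "C2", "C3", "O"),
      to   = c("C1", "C2", "C3", "O",  "Cf"),
      fwd  = c("a",  "a",  "a",  "ko", "kci0"),
      bwd  = c("b",  "b",  "b",  "kc", "kcr0"),
      z    = c(3, 3, 3, 4, 0)),
    name = "Kv1-dN")
}

# directed edge table (one row per direction) used by generator/gating code
.directed_edges <- function(scheme) {
  e <- scheme$edges
  rbind(
    data.frame(from = e$from, to = e$to, rate = e$fwd, z = e$z),
    data.frame(from = e$to, to = e$from, rate = e$bwd, z = -e$z))
}
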