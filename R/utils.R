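#' Derive a reproducible sub-stream seed
#'
#' Deterministically maps a master seed plus an arbitrary sequence of string
#' or numeric tags to a new integer seed below 2^31. Used throughout the
#' package so that every permutation stream (per gene set, per reduction
#' step, per replicate, per fold) is reproducible from one master seed while
#' remaining decoupled from the others.
#'
#' @param seed integer master seed.
#' @param ... further tags (coerced to character) identifying the sub-stream.
#' @return a single integer in `[0, 2147483628]`.
#' @export
#' @examples
#' derive_seed(1, "stage1", "GO_SET_A")
derive_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "\r")
  bytes <- utf8ToInt(key)
  h <- 0
  # simple 31-ary rolling hash modulo a prime < 2^31; platform independent
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  as.integer(h)
}

.input_error <- function(msg) {
  stop(errorCondition(msg, class = c("samgsr_input_error", "error")))
}

.degenerate_error <- function(msg) {
  stop(errorCondition(msg, class = c("samgsr_degenerate_error", "error")))
}

# infer (case, control) from a label vector when not given explicitly:
# the lexicographically first distinct label is taken as the case class
.infer_classes <- function(labels, case_label = NULL, control_label = NULL) {
  lev <- sort(unique(as.character(labels)), method = "radix")
  if (is.null(case_label) && is.null(control_label)) {
    if (length(lev) != 2L)
      .input_error(sprintf(
        "labels have %d distinct classes; give case_label/control_label for a 2-class analysis",
        length(lev)))
    return(c(case = lev[1L], control = lev[2L]))
  }
  if (is.null(control_label)) control_label <- setdiff(lev, case_label)[1L]
  if (is.null(case_label)) case_label <- setdiff(lev, control_label)[1L]
  for (l in c(case_label, control_label))
    if (!l %in% lev) .input_error(sprintf("unknown class label '%s'", l))
  c(case = case_label, control = control_label)
}
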