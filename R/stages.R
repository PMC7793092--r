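#' Sleep stage alphabets
#'
#' Five-symbol polysomnography staging (`W`, `N1`, `N2`, `N3`, `REM`),
#' the collapsed three-class alphabet (`W`, `NREM`, `REM`) used by the
#' classifier, and the binary sleep/wake view.
#'
#' @name stage-alphabets
#' @keywords internal
NULL

STAGES5 <- c("W", "N1", "N2", "N3", "REM")
STAGES3 <- c("W", "NREM", "REM")
EPOCH_SEC <- 30

#' Collapse five-stage labels
#'
#' Deterministically maps `W/N1/N2/N3/REM` labels to the three-class
#' alphabet (`N1`-`N3` become `NREM`) or to binary `wake`/`sleep`.
#'
#' @param labels Character vector of stage labels (5-, 3-, or 2-symbol).
#' @param to `"three"` or `"binary"`.
#' @return Character vector of the same length.
#' @export
#' @examples
#' collapse_stages(c("W", "N2", "REM"), "binary")
collapse_stages <- function(labels, to = c("three", "binary")) {
  to <- match.arg(to)
  labels <- as.character(labels)
  bad <- !labels %in% c(STAGES5, STAGES3, "sleep", "wake") & !is.na(labels)
  if (any(bad)) {
    stop("unknown stage label(s): ", paste(unique(labels[bad]), collapse = ", "))
  }
  three <- ifelse(labels %in% c("N1", "N2", "N3"), "NREM", labels)
  if (to == "three") {
    if (any(three %in% c("sleep", "wake"))) {
      stop("cannot expand binary labels to three classes")
    }
    return(three)
  }
  ifelse(three %in% c("NREM", "REM", "sleep"), "sleep",
         ifelse(is.na(three), NA_character_, "wake"))
}

#' Construct a hypnogram
#'
#' A hypnogram is a per-epoch sequence of stage labels on the fixed 30-s
#' grid, stored in the three-class alphabet (`W`, `NREM`, `REM`).
#' Five-stage input is collapsed on construction.
#'
#' @param labels Character vector of stage labels.
#' @param epoch_len Epoch length in seconds (fixed at 30).
#' @return An object of class `hypnogram` (character vector with
#'   attribute `epoch_len`).
#' @export
hypnogram <- function(labels, epoch_len = EPOCH_SEC) {
  if (length(labels) < 1) stop("a hypnogram needs at least one epoch")
  labels <- collapse_stages(labels, "three")
  structure(labels, class = "hypnogram", epoch_len = epoch_len)
}

#' Binary sleep/wake view of a hypnogram
#'
#' @param h A [hypnogram()] or character vector of stage labels.
#' @return Character vector of `"sleep"` / `"wake"`.
#' @export
as_sleep_wake <- function(h) {
  collapse_stages(unclass(h), "binary")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = STAGES3))
  cat(sprintf("<hypnogram> %d epochs (%.1f min): W=%d NREM=%d REM=%d\n",
              length(x), length(x) * attr(x, "epoch_len") / 60,
              tab[["W"]], tab[["NREM"]], tab[["REM"]]))
  invisible(x)
}
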