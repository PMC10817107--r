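#' Canonical sleep-stage levels
#'
#' The five AASM scoring classes in the package's fixed order:
#' wake (`W`), the three non-REM depths (`N1`, `N2`, `N3`) and rapid eye
#' movement sleep (`REM`). Every function in the package that consumes or
#' produces stage labels uses this ordering, so confusion matrices, metric
#' tables and one-hot encodings are always aligned.
#'
#' @return Character vector `c("W", "N1", "N2", "N3", "REM")`.
#' @export
#' @examples
#' stage_levels()
stage_levels <- function() c("W", "N1", "N2", "N3", "REM")

#' Coerce stage tokens to the canonical factor
#'
#' Accepts character tokens (case-insensitive). `"R"` is accepted as an
#' alias for `"REM"`, the abbreviation used on hypnogram figures; output
#' always uses the full token.
#'
#' @param x Character vector (or factor) of stage tokens.
#' @return Factor with levels [stage_levels()].
#' @export
#' @examples
#' stage_factor(c("w", "N1", "R"))
stage_factor <- function(x) {
  x <- toupper(as.character(x))
  x[x == "R"] <- "REM"
  bad <- !(x %in% stage_levels()) & !is.na(x)
  if (any(bad)) {
    stop("unknown sleep-stage token(s): ",
         paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  factor(x, levels = stage_levels())
}

# Integer code 0..4 for a stage factor (W = 0, ..., REM = 4).
stage_code <- function(x) as.integer(stage_factor(x)) - 1L
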