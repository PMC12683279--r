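#' @keywords internal
"_PACKAGE"

# Enum vocabularies used throughout the sample metadata. Tokens are
# lower_snake_case and appear verbatim in metadata files.
SAMPLE_CLASSES <- c("skin", "object", "negative_control")
SITES <- c("forehead", "left_hand", "right_hand", "none")
TIME_POINTS <- c("t0", "t1", "t2", "none")
OBJECT_TYPES <- c("cell_phone", "door_handle", "fabric", "plastic", "none")

# Sentinel used for "no value" in metadata columns and for the subject id of
# negative controls.
NONE <- "none"

# Literal used in taxonomy files for taxa unresolved at a rank.
UNCLASSIFIED <- "UNCLASSIFIED"

vm_stop <- function(..., class = "viromark_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

vm_validation_stop <- function(...) {
  vm_stop(..., class = c("viromark_validation_error", "viromark_error"))
}

vm_warn <- function(...) {
  warning(paste0(...), call. = FALSE)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state so that seeded package functions never disturb
#' the user's random stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate under the seed.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    vm_validation_stop("`seed` must be a single non-missing integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Match one token against an enum vocabulary, with an error listing the
# allowed tokens (metadata files are hand-editable, so errors must name them).
match_enum <- function(value, allowed, what) {
  if (length(value) != 1L || is.na(value) || !value %in% allowed) {
    vm_validation_stop(
      "invalid ", what, " token ", deparse(as.character(value)),
      "; allowed: ", paste(allowed, collapse = ", ")
    )
  }
  value
}
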