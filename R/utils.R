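# Shared internal helpers: organ vocabulary, argument checks, transforms.

# Axial order along the hydraulic path, leaf (1) -> very fine root (7).
ORGAN_LEVELS <- c("leaf", "twig", "branch", "trunk",
                  "coarse_root", "fine_root", "very_fine_root")

# Organs whose records carry an external diameter D (leaves have none).
STEM_ORGANS <- c("twig", "branch", "trunk")
ROOT_ORGANS <- c("coarse_root", "fine_root", "very_fine_root")

#' Organ vocabulary in axial order
#'
#' Returns the seven organ classes recognized in conduit tables, ordered by
#' axial position from the leaf tip to the very fine roots.
#'
#' @return Character vector of length 7.
#' @export
organ_levels <- function() ORGAN_LEVELS

stop_validation <- function(...) {
  stop(structure(class = c("xt_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_positive <- function(x, name, finite = TRUE) {
  if (length(x) == 0L) stop_validation(name, " is empty")
  bad <- !is.finite(x) | x <= 0
  if (!finite) bad <- (is.na(x) | (is.finite(x) & x <= 0))
  if (any(bad)) {
    stop_validation(name, " must be positive and finite; offending index ",
                    which(bad)[1L], " (value ", x[which(bad)[1L]], ")")
  }
  invisible(x)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation(name, " must be a single finite number")
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_validation(name, " = ", x, " is outside the allowed range")
  invisible(x)
}

# Transform labels are "<x>-<y>"; each side is "log10", "linear" or "none".
TRANSFORMS <- c("log10-log10", "log10-linear", "linear-log10", "none")

apply_transform <- function(x, y, transform) {
  transform <- match.arg(transform, TRANSFORMS)
  parts <- if (transform == "none") c("linear", "linear")
           else strsplit(transform, "-", fixed = TRUE)[[1L]]
  tf1 <- function(v, lab, axis) {
    if (identical(lab, "log10")) {
      check_positive(v, paste0(axis, " (log10 transform requested)"))
      log10(v)
    } else v
  }
  list(x = tf1(x, parts[1L], "x"), y = tf1(y, parts[2L], "y"),
       transform = transform)
}

# Seed substreams: derive a deterministic child seed < 2^31 from a root seed.
child_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + index * 30269) %% 2147483647
}

format_p <- function(p) {
  if (!is.finite(p)) return(NA_character_)
  if (p < 2.22e-16) "< 2.22e-16" else format(p, digits = 3)
}
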