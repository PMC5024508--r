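# Internal helpers shared across modules.

# Counts are rounded half-away-from-zero, and only at presentation;
# all internal arithmetic stays in full precision.
round_count <- function(x) sign(x) * floor(abs(x) + 0.5)

is_fraction <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)

stop_field <- function(field, constraint) {
  stop(sprintf("invalid value for '%s': %s", field, constraint), call. = FALSE)
}

check_fraction <- function(x, field) {
  if (!is_fraction(x)) stop_field(field, "must be a fraction in [0, 1]")
  invisible(x)
}

check_enforcement <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < 0 || x > 10) {
    stop_field(field, "must be an integer score in [0, 10]")
  }
  invisible(as.integer(x))
}

check_enum <- function(x, levels, field) {
  if (!is.character(x) || length(x) != 1L || !(x %in% levels)) {
    stop_field(field, paste0("must be one of: ", paste(levels, collapse = ", ")))
  }
  invisible(x)
}

# Complement-product pooling of independent proportional effects:
# 1 - prod(1 - e). Order-invariant, bounded in [0, 1) for e in [0, 1).
complement_product <- function(e) 1 - prod(1 - e)

`%||%` <- function(a, b) if (is.null(a)) b else a
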