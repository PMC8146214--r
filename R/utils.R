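# Internal argument checking helpers.

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          allow_vector = FALSE) {
  if (!is.numeric(x) || (!allow_vector && length(x) != 1L)) {
    stop(sprintf("`%s` must be a %s numeric value", name,
                 if (allow_vector) "finite" else "single"), call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  }
  if (any(x < lower) || any(x > upper)) {
    stop(sprintf("`%s` must be in [%s, %s]", name, format(lower),
                 format(upper)), call. = FALSE)
  }
  invisible(x)
}

assert_fraction <- function(x, name) {
  assert_number(x, name, lower = 0, upper = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deep-merge override list into base list (names in `over` win)
merge_constants <- function(base, over) {
  if (is.null(over)) return(base)
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      base[[nm]] <- merge_constants(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}
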