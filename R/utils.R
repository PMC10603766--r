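# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}

assert_image <- function(image, name = "image") {
  if (!is.numeric(image) || !(length(dim(image)) %in% c(2L, 3L)))
    stopf("`%s` must be a numeric matrix or height x width x channels array", name)
  invisible(image)
}

assert_mask <- function(mask, name = "mask") {
  if (!is.logical(mask) || length(dim(mask)) != 2L)
    stopf("`%s` must be a logical matrix (rows = y, cols = x)", name)
  invisible(mask)
}

# round a numeric intensity image to 8-bit range
clip8 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  round(x)
}
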