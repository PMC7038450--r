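# internal helpers shared across modules

# Canonical pixel ordering used everywhere: row 1 columns 1..10, then
# row 2 columns 1..10 (20 values per frame).
pixel_cols <- function() {
  c(paste0("r1c", 1:10), paste0("r2c", 1:10))
}

# 0-based geometry for moment computations: x = column, y = row.
pixel_x <- function() rep(0:9, times = 2)
pixel_y <- function() rep(0:1, each = 10)

ADC_MAX <- 4095L

# Run expr with the RNG seeded, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Excess kurtosis with population moments; zero-variance input is defined
# as 0 so constant features stay finite.
excess_kurtosis <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= .Machine$double.eps * max(1, m^2)) return(0)
  mean((x - m)^4) / m2^2 - 3
}

`%||%` <- function(a, b) if (is.null(a)) b else a
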