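# shared internal helpers

.assertScalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("`%s` must lie in [%s, %s]", name, lower, upper),
      call. = FALSE
    )
  }
  invisible(x)
}

.asCount <- function(x, name, min = 1L) {
  if (length(x) != 1 || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

# polynomial rolling hash of a deparsed object; stamps outputs with an
# effective-configuration fingerprint without external dependencies
.configHash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

# truncated-at-zero normal draws (reversal intervals)
.rtruncnorm0 <- function(n, mean, sd) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mean, sd)
      if (x > 0) break
    }
    out[i] <- x
  }
  out
}

# does every pocket sphere fit inside the tapering cone?
.pocketsInsideCone <- function(truth) {
  p <- truth@pockets
  if (nrow(p) == 0) {
    return(logical(0))
  }
  a0 <- truth@baseAxes[1]
  b0 <- truth@baseAxes[2]
  H <- truth@apexHeight
  vapply(seq_len(nrow(p)), function(i) {
    r <- p$diameter[i] / 2
    hs <- c(max(p$z[i] - r, 0), p$z[i], p$z[i] + r)
    if (p$z[i] - r < -1e-9 || p$z[i] + r > H) {
      return(FALSE)
    }
    all(vapply(hs, function(h) {
      s <- 1 - h / H
      ae <- a0 * s - r
      be <- b0 * s - r
      if (ae <= 0 || be <= 0) {
        return(FALSE)
      }
      (p$x[i] / ae)^2 + (p$y[i] / be)^2 <= 1
    }, logical(1)))
  }, logical(1))
}
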