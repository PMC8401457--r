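# Independent numeric oracles: pure dense-grid scans, no refinement, so
# they share no code path with the package's feature extraction.

oracle_argmax <- function(f, rng, n = 200001L) {
  xs <- seq(rng[1], rng[2], length.out = n)
  v <- f(xs)
  list(x = xs[which.max(v)], value = max(v))
}

oracle_crossing <- function(f, rng, level, n = 200001L) {
  xs <- seq(rng[1], rng[2], length.out = n)
  v <- f(xs)
  d <- v - level
  k <- which(d[-n] * d[-1] <= 0)[1]
  if (is.na(k)) return(NA_real_)
  xs[k] + (level - v[k]) * (xs[k + 1] - xs[k]) / (v[k + 1] - v[k])
}

# closed-form 4PL written out independently of logistic4()
f4pl <- function(x, c, d, b, e) c + (d - c) / (1 + exp(b * (x - e)))

tiny_plate_csv <- function(text = "Time,A1,A2\n0,100,101\n1,110,112\n2,150,149") {
  f <- tempfile(fileext = ".csv")
  writeLines(text, f)
  f
}

quiet_param_table <- function(...) suppressMessages(build_param_table(...))
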