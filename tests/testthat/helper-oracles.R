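# Independent oracles used across the test suite.

# Brute-force Vietoris-Rips persistence (dims 0 and 1) by standard boundary
# matrix reduction over Z/2 on the FULL complex (vertices, edges, triangles),
# with the simplex-wise order (diameter, dimension, lexicographic index).
# Feasible for clouds of up to ~15 points; completely independent of the
# package's cohomology engine.
rips_oracle <- function(points) {
  n <- nrow(points)
  d <- as.matrix(dist(points))
  simp <- list()   # each: list(vertices, diam, dim)
  for (i in seq_len(n)) simp[[length(simp) + 1L]] <- list(v = i, diam = 0, dim = 0L)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      simp[[length(simp) + 1L]] <- list(v = c(i, j), diam = d[i, j], dim = 1L)
  }
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n)
      simp[[length(simp) + 1L]] <- list(v = c(i, j, k),
                                        diam = max(d[i, j], d[i, k], d[j, k]),
                                        dim = 2L)
  }
  diam <- vapply(simp, `[[`, numeric(1), "diam")
  dims <- vapply(simp, `[[`, integer(1), "dim")
  lex <- vapply(simp, function(s) paste(sprintf("%04d", s$v), collapse = ""),
                character(1))
  ord <- order(diam, dims, lex)
  simp <- simp[ord]
  diam <- diam[ord]
  dims <- dims[ord]
  key <- vapply(simp, function(s) paste(s$v, collapse = "-"), character(1))
  pos <- setNames(seq_along(simp), key)

  m <- length(simp)
  columns <- vector("list", m)          # boundary columns as sorted row indices
  for (j in seq_len(m)) {
    s <- simp[[j]]
    if (s$dim == 0L) { columns[[j]] <- integer(0); next }
    faces <- lapply(seq_along(s$v), function(r) s$v[-r])
    columns[[j]] <- sort(unname(pos[vapply(faces, paste, character(1),
                                           collapse = "-")]))
  }
  low_of <- integer(m); low_of[] <- NA_integer_  # row -> column with that low
  pair <- integer(m); pair[] <- NA_integer_
  for (j in seq_len(m)) {
    col <- columns[[j]]
    while (length(col) > 0) {
      low <- max(col)
      other <- low_of[low]
      if (is.na(other)) break
      col <- sort(union(setdiff(col, columns[[other]]),
                        setdiff(columns[[other]], col)))
    }
    columns[[j]] <- col
    if (length(col) > 0) {
      low <- max(col)
      low_of[low] <- j
      pair[low] <- j
    }
  }
  res <- data.frame(dimension = integer(0), birth = numeric(0),
                    death = numeric(0))
  for (i in seq_len(m)) {
    if (!is.na(pair[i])) {           # i is a birth simplex paired with pair[i]
      b <- diam[i]; dd <- diam[pair[i]]
      if (dd > b) res <- rbind(res, data.frame(dimension = dims[i],
                                               birth = b, death = dd))
    } else if (length(columns[[i]]) == 0 && is.na(low_of[i])) {
      # zero column that is never a pivot: essential class
      res <- rbind(res, data.frame(dimension = dims[i], birth = diam[i],
                                   death = Inf))
    }
  }
  res <- res[res$dimension <= 1, , drop = FALSE]
  res <- res[order(res$dimension, res$birth, res$death), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Sort a persistence diagram into oracle-comparable canonical form.
canon_diagram <- function(dg) {
  dg <- as.data.frame(dg)[, c("dimension", "birth", "death")]
  dg <- dg[order(dg$dimension, dg$birth, dg$death), , drop = FALSE]
  rownames(dg) <- NULL
  dg
}

# Mann-Whitney U by exhaustive pair enumeration (x-side wins + half ties).
u_oracle <- function(x, y) {
  cmp <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
  sum(cmp)
}

# Band power via a plain periodogram, integrating |FFT|^2 over [lo, hi] Hz.
bandpower_oracle <- function(x, fs, lo, hi) {
  n <- length(x)
  spec <- abs(fft(x - mean(x)))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  keep <- freqs >= lo & freqs <= hi & freqs <= fs / 2
  sum(spec[keep])
}

# Pooled regression metrics, hand-spelled.
regmetrics_oracle <- function(truth, pred) {
  list(r2 = 1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2),
       mse = mean((truth - pred)^2),
       mae = mean(abs(truth - pred)),
       mape = mean(abs(truth - pred) / abs(truth)) * 100)
}
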