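# Independent brute-force dynamic-programming oracles, written directly
# from the textbook recurrences. They share the package's documented
# conventions (gap of length L costs open + L * ext; traceback prefers
# diagonal, then gap-in-query, then gap-in-template; gap opening preferred
# over extension on ties; best cell is the first maximum in row-major
# order) but none of its code.

oracle_submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Local (Smith-Waterman) affine-gap alignment, full matrices.
oracle_sw <- function(q, t, go = 11, ge = 1) {
  S <- oracle_submat()
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  n <- length(qc); m <- length(tc)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)   # gap in query (template consumed)
  F_ <- matrix(NEG, n + 1, m + 1)  # gap in template (query consumed)
  for (i in 1:n) {
    for (j in 1:m) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - go - ge, E[i + 1, j] - ge)
      F_[i + 1, j + 1] <- max(H[i, j + 1] - go - ge, F_[i, j + 1] - ge)
      H[i + 1, j + 1] <- max(0, H[i, j] + S[qc[i], tc[j]],
                             E[i + 1, j + 1], F_[i + 1, j + 1])
    }
  }
  best <- max(H)
  if (best <= 0) return(list(score = 0, identity = 0, coverage = 0))
  # first maximum in row-major order
  hit <- which(t(H) == best)[1] - 1
  bi <- hit %/% (m + 1)
  bj <- hit %% (m + 1)
  i <- bi; j <- bj
  cols <- 0; ident <- 0; jmin <- m + 1; jmax <- 0
  state <- "H"
  while (i > 0 && j > 0) {
    if (state == "H") {
      h <- H[i + 1, j + 1]
      if (h == 0) break
      diag <- H[i, j] + S[qc[i], tc[j]]
      if (h == diag) {
        cols <- cols + 1
        if (qc[i] == tc[j]) ident <- ident + 1
        jmin <- min(jmin, j); jmax <- max(jmax, j)
        i <- i - 1; j <- j - 1
      } else if (h == E[i + 1, j + 1]) state <- "E"
      else state <- "F"
    } else if (state == "E") {
      cols <- cols + 1
      jmin <- min(jmin, j); jmax <- max(jmax, j)
      opened <- E[i + 1, j + 1] == H[i + 1, j] - go - ge
      j <- j - 1
      if (opened) state <- "H"
    } else {
      cols <- cols + 1
      opened <- F_[i + 1, j + 1] == H[i, j + 1] - go - ge
      i <- i - 1
      if (opened) state <- "H"
    }
  }
  list(score = best,
       identity = 100 * ident / cols,
       coverage = 100 * (jmax - jmin + 1) / m)
}

# Global (Needleman-Wunsch) affine-gap alignment identity fraction,
# gap columns counted in the denominator.
oracle_nw_identity <- function(a, b, go = 11, ge = 1) {
  S <- oracle_submat()
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  NEG <- -1e9
  H <- matrix(NEG, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F_ <- matrix(NEG, n + 1, m + 1)
  H[1, 1] <- 0
  for (j in 1:m) { E[1, j + 1] <- -go - ge * j; H[1, j + 1] <- E[1, j + 1] }
  for (i in 1:n) { F_[i + 1, 1] <- -go - ge * i; H[i + 1, 1] <- F_[i + 1, 1] }
  for (i in 1:n) {
    for (j in 1:m) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - go - ge, E[i + 1, j] - ge)
      F_[i + 1, j + 1] <- max(H[i, j + 1] - go - ge, F_[i, j + 1] - ge)
      H[i + 1, j + 1] <- max(H[i, j] + S[ac[i], bc[j]],
                             E[i + 1, j + 1], F_[i + 1, j + 1])
    }
  }
  i <- n; j <- m; cols <- 0; ident <- 0
  state <- "H"
  while (i > 0 || j > 0) {
    if (i == 0) { cols <- cols + 1; j <- j - 1; next }
    if (j == 0) { cols <- cols + 1; i <- i - 1; next }
    if (state == "H") {
      h <- H[i + 1, j + 1]
      diag <- H[i, j] + S[ac[i], bc[j]]
      if (h == diag) {
        cols <- cols + 1
        if (ac[i] == bc[j]) ident <- ident + 1
        i <- i - 1; j <- j - 1
      } else if (h == E[i + 1, j + 1]) state <- "E"
      else state <- "F"
    } else if (state == "E") {
      cols <- cols + 1
      opened <- E[i + 1, j + 1] == H[i + 1, j] - go - ge
      j <- j - 1
      if (opened) state <- "H"
    } else {
      cols <- cols + 1
      opened <- F_[i + 1, j + 1] == H[i, j + 1] - go - ge
      i <- i - 1
      if (opened) state <- "H"
    }
  }
  ident / cols
}

# Closed-form ordinary least squares.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

AA20_TEST <- c("A","C","D","E","F","G","H","I","K","L",
               "M","N","P","Q","R","S","T","V","W","Y")

random_aa <- function(len) paste(sample(AA20_TEST, len, replace = TRUE),
                                 collapse = "")
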