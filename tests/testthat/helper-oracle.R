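# Independent alignment oracle: plain-R Gotoh global alignment with affine
# gaps (cost of a gap of length L = open + ext * L), high-road traceback.
# Kept deliberately separate from the package's alignment path so the two
# can be compared on random pairs.

.oracle_blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

nw_oracle <- function(a, b, mat = .oracle_blosum62, open = 12, ext = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in a match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in a gap in b (a consumed)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in a gap in a (b consumed)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - ext * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -open - ext * (j - 1)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- mat[av[i - 1], bv[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                   Y[i - 1, j] - open - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext,
                   X[i, j - 1] - open - ext)
  }
  score <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  # high-road traceback: prefer match, then gap-in-b, then gap-in-a
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  n_sap <- 0L
  while (i > 1 || j > 1) {
    if (state == 1L) {
      if (av[i - 1] != bv[j - 1]) n_sap <- n_sap + 1L
      s <- mat[av[i - 1], bv[j - 1]]
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      state <- which.max(abs(prev - M[i, j]) < 1e-9)
      i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      prev <- c(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                Y[i - 1, j] - open - ext)
      state <- which.max(abs(prev - X[i, j]) < 1e-9)
      i <- i - 1
    } else {
      prev <- c(M[i, j - 1] - open - ext, X[i, j - 1] - open - ext,
                Y[i, j - 1] - ext)
      state <- c(1L, 2L, 3L)[which.max(abs(prev - Y[i, j]) < 1e-9)]
      j <- j - 1
    }
  }
  list(score = score, n_sap = n_sap)
}

# set of n_sap values achievable over ALL co-optimal global alignments:
# forward DP propagating, per cell and state, the n_sap sets of optimal
# prefixes (a prefix lies on some optimal path iff it attains the DP value
# of its end state and the end state reaches the global optimum).
nw_oracle_nsap_set <- function(a, b, mat = .oracle_blosum62, open = 12,
                               ext = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  SM <- SX <- SY <- matrix(list(integer()), n + 1, m + 1)
  M[1, 1] <- 0; SM[[1, 1]] <- 0L
  for (i in 2:(n + 1)) { X[i, 1] <- -open - ext * (i - 1); SX[[i, 1]] <- 0L }
  for (j in 2:(m + 1)) { Y[1, j] <- -open - ext * (j - 1); SY[[1, j]] <- 0L }
  pick <- function(vals, sets, target)
    sort(unique(unlist(sets[abs(vals - target) < 1e-9])))
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- mat[av[i - 1], bv[j - 1]]
    mis <- as.integer(av[i - 1] != bv[j - 1])
    vals <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
    M[i, j] <- max(vals) + s
    SM[[i, j]] <- pick(vals, list(SM[[i - 1, j - 1]], SX[[i - 1, j - 1]],
                                  SY[[i - 1, j - 1]]), max(vals)) + mis
    vals <- c(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
              Y[i - 1, j] - open - ext)
    X[i, j] <- max(vals)
    SX[[i, j]] <- pick(vals, list(SM[[i - 1, j]], SX[[i - 1, j]],
                                  SY[[i - 1, j]]), X[i, j])
    vals <- c(M[i, j - 1] - open - ext, X[i, j - 1] - open - ext,
              Y[i, j - 1] - ext)
    Y[i, j] <- max(vals)
    SY[[i, j]] <- pick(vals, list(SM[[i, j - 1]], SX[[i, j - 1]],
                                  SY[[i, j - 1]]), Y[i, j])
  }
  fin <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  list(score = max(fin),
       nsap_set = pick(fin, list(SM[[n + 1, m + 1]], SX[[n + 1, m + 1]],
                                 SY[[n + 1, m + 1]]), max(fin)))
}
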