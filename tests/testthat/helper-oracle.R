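# Independent dynamic-programming alignment oracle.
#
# Re-implements, in plain R, the alignment variant used for V-REGION
# identity: the pattern aligned end-to-end (global) inside a freely chosen
# window of the subject (local), with affine gaps (a gap of length L costs
# open + L * ext).  Written against the scoring definition only --- it shares
# no code with the package's Biostrings-backed path --- and returns both the
# optimal score and the identity (matches / alignment columns) of one
# optimal alignment recovered by traceback.
oracle_glocal <- function(pattern, subject, match = 2, mismatch = -3,
                          gap_open = 6, gap_ext = 1) {
  p <- strsplit(toupper(pattern), "")[[1]]
  s <- strsplit(toupper(subject), "")[[1]]
  m <- length(p)
  n <- length(s)
  NEG <- -1e9
  # state matrices: M diag, X pattern-vs-gap (deletion in subject),
  # Y subject-vs-gap (insertion in subject)
  M <- matrix(NEG, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  M[1, ] <- 0                       # free subject prefix (local in subject)
  for (i in 2:(m + 1)) {
    X[i, 1] <- -(gap_open + (i - 1) * gap_ext)
    for (j in seq_len(n + 1)) {
      if (j > 1) {
        sub <- if (p[i - 1] == s[j - 1]) match else mismatch
        M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1],
                       Y[i - 1, j - 1]) + sub
        Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext,
                       Y[i, j - 1] - gap_ext,
                       X[i, j - 1] - gap_open - gap_ext)
      }
      X[i, j] <- max(X[i, j],
                     M[i - 1, j] - gap_open - gap_ext,
                     X[i - 1, j] - gap_ext,
                     Y[i - 1, j] - gap_open - gap_ext)
    }
  }
  ends <- pmax(M[m + 1, ], X[m + 1, ])
  score <- max(ends)
  j <- which.max(ends)              # leftmost optimal subject end
  # traceback (prefer M, then X, then Y on ties)
  state <- if (M[m + 1, j] >= X[m + 1, j]) "M" else "X"
  i <- m + 1
  cols <- 0L
  matches <- 0L
  while (i > 1) {
    if (state == "M") {
      sub <- if (p[i - 1] == s[j - 1]) match else mismatch
      if (p[i - 1] == s[j - 1]) matches <- matches + 1L
      cols <- cols + 1L
      prev <- M[i, j] - sub
      state <- if (abs(M[i - 1, j - 1] - prev) < 1e-9) "M"
               else if (abs(X[i - 1, j - 1] - prev) < 1e-9) "X" else "Y"
      i <- i - 1; j <- j - 1
    } else if (state == "X") {
      cols <- cols + 1L
      cur <- X[i, j]
      state <- if (abs(X[i - 1, j] - gap_ext - cur) < 1e-9) "X"
               else if (abs(M[i - 1, j] - gap_open - gap_ext - cur) < 1e-9)
                 "M" else "Y"
      i <- i - 1
    } else {
      cols <- cols + 1L
      cur <- Y[i, j]
      state <- if (abs(Y[i, j - 1] - gap_ext - cur) < 1e-9) "Y"
               else if (abs(M[i, j - 1] - gap_open - gap_ext - cur) < 1e-9)
                 "M" else "X"
      j <- j - 1
    }
  }
  list(score = score,
       identity_pct = scfvtools::round_half_up(100 * matches / cols, 2))
}

# brute-force edit distance (unit costs), for the linker locator oracle
oracle_edit_distance <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(a) + 1, length(b) + 1)
  d[, 1] <- 0:length(a)
  d[1, ] <- 0:length(b)
  for (i in seq_along(a)) for (j in seq_along(b))
    d[i + 1, j + 1] <- min(d[i, j] + (a[i] != b[j]), d[i, j + 1] + 1L,
                           d[i + 1, j] + 1L)
  d[length(a) + 1, length(b) + 1]
}

# random mutated copy of a sequence (substitutions + occasional indels)
mutate_seq <- function(seq, n_sub = 0, n_ins = 0, n_del = 0) {
  s <- strsplit(seq, "")[[1]]
  if (n_sub > 0) {
    pos <- sample(length(s), n_sub)
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  }
  if (n_ins > 0) for (k in seq_len(n_ins)) {
    p <- sample(length(s), 1)
    s <- append(s, sample(c("A", "C", "G", "T"), 1), after = p)
  }
  if (n_del > 0) for (k in seq_len(n_del)) {
    p <- sample(length(s), 1)
    s <- s[-p]
  }
  paste(s, collapse = "")
}
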