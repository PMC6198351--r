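# Independent brute-force oracles, deliberately coded with different
# algorithms than the package implementation.

# internal-priming decision by character-level scanning:
#  rule 1: >= 8 consecutive A
#  rule 2: G, a run of >= 4 A, G, a run of >= 3 A, G (contiguous)
#  rule 3: more than 12 A in total
oracle_ip_decision <- function(window) {
  chars <- strsplit(window, "")[[1]]
  run <- 0L; rule1 <- FALSE
  for (ch in chars) {
    if (ch == "A") { run <- run + 1L; if (run >= 8L) rule1 <- TRUE }
    else run <- 0L
  }
  rule2 <- FALSE
  gpos <- which(chars == "G")
  for (i in gpos) {
    for (j in gpos[gpos > i + 4L]) {
      if (!all(chars[(i + 1L):(j - 1L)] == "A")) next
      for (k in gpos[gpos > j + 3L]) {
        if (all(chars[(j + 1L):(k - 1L)] == "A")) { rule2 <- TRUE; break }
      }
    }
  }
  rule3 <- sum(chars == "A") > 12L
  rule1 || rule2 || rule3
}

# single-linkage clusters as connected components of the all-pairs
# "same chrom, same strand, distance <= max_gap" graph (BFS)
oracle_cluster_members <- function(chrom, strand, position, max_gap = 24L) {
  n <- length(position)
  adj <- outer(position, position, function(a, b) abs(a - b) <= max_gap) &
    outer(chrom, chrom, "==") & outer(strand, strand, "==")
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# canonical form of a clustering for comparison: sorted member-position
# sets per component
canon_clusters <- function(chrom, strand, position, comp) {
  keys <- split(paste(chrom, strand, position), comp)
  unname(lapply(keys[order(vapply(keys, min, ""))], sort))
}

# trend test by expansion to one (group, score) observation per read
oracle_trend <- function(case_counts, control_counts, scores) {
  g <- c(rep(1, sum(case_counts)), rep(0, sum(control_counts)))
  s <- c(rep(scores, case_counts), rep(scores, control_counts))
  N <- length(g)
  r <- suppressWarnings(stats::cor(g, s))
  if (is.na(r)) r <- 0
  m2 <- (N - 1) * r^2
  list(r = r, m2 = m2, p = stats::pchisq(m2, 1, lower.tail = FALSE))
}

# textbook step-up BH: p_(i) * m / i with monotone enforcement from the top
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# two-sided Fisher p for a 2x2 table by direct hypergeometric enumeration
oracle_fisher2x2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p0 <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

random_window <- function(n = 20L) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(0.4, 0.2, 0.2, 0.2)), collapse = "")
}

# embed a motif at a random offset inside a random window
embed_motif <- function(motif, n = 20L) {
  pad <- n - nchar(motif)
  left <- sample(0:pad, 1)
  paste0(paste(sample(c("A", "C", "G", "T"), left, replace = TRUE), collapse = ""),
         motif,
         paste(sample(c("A", "C", "G", "T"), pad - left, replace = TRUE),
               collapse = ""))
}

random_2xk_table <- function(max_k = 5L, max_n = 200L) {
  k <- sample(2:max_k, 1)
  N <- sample(2:max_n, 1)
  n1 <- sample(0:N, 1)
  scores <- sort(sample(1:2000, k))
  case <- as.integer(stats::rmultinom(1, n1, rep(1 / k, k)))
  control <- as.integer(stats::rmultinom(1, N - n1, rep(1 / k, k)))
  list(case = case, control = control, scores = scores)
}
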