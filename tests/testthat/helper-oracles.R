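# Fixture loaders (memoised per test run)

.fixenv <- new.env(parent = emptyenv())

fixCompounds <- function() {
  if (is.null(.fixenv$tab))
    .fixenv$tab <- readCompoundTable(table1Path("compounds"))
  .fixenv$tab
}

fixContents <- function() {
  if (is.null(.fixenv$vs))
    .fixenv$vs <- readContentMatrix(table1Path("contents"))
  .fixenv$vs
}

fixOAV <- function() {
  if (is.null(.fixenv$oav))
    .fixenv$oav <- oavMatrix(cultivarMeans(fixContents()), fixCompounds())
  .fixenv$oav
}

# Independent Benjamini-Hochberg step-up oracle:
# q_(i) = min_{j >= i} min(1, p_(j) * m / j), back in input order.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- pmin(1, p[o] * m / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Exhaustive concordant-pair AUC oracle: P(score+ > score-) + 0.5 P(tie)
aucOracle <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Brute-force greedy Ward oracle working directly on coordinates:
# at each step merge the pair of clusters with the smallest increase in
# within-cluster ESS; height = sqrt(2 * deltaESS).  Returns the partition
# after each merge (as canonical strings) and the merge heights.
wardOracle <- function(x) {
  ess <- function(idx) {
    sub <- x[idx, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- NULL; bestd <- Inf
    for (i in seq_along(clusters)[-length(clusters)])
      for (j in (i + 1):length(clusters)) {
        dd <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (dd < bestd) { bestd <- dd; best <- c(i, j) }
      }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
    heights <- c(heights, sqrt(2 * bestd))
    partitions[[length(partitions) + 1]] <- sort(vapply(
      clusters, function(cl) paste(sort(cl), collapse = ","), character(1)))
  }
  list(heights = heights, partitions = partitions)
}

# partitions implied by an hcaWard result, same canonical form
hcaPartitions <- function(res, n) {
  members <- as.list(seq_len(n))      # singleton members by item
  clusters <- lapply(seq_len(n), function(i) i)
  alive <- rep(TRUE, n)
  stepMembers <- vector("list", n - 1)
  slot <- integer(n - 1)              # which item slot holds merge s
  out <- vector("list", n - 1)
  get <- function(code) if (code < 0) -code else stepMembers[[code]]
  pos <- function(code) if (code < 0) -code else slot[code]
  for (s in seq_len(n - 1)) {
    a <- res$merge[s, 1]; b <- res$merge[s, 2]
    ia <- pos(a); ib <- pos(b)
    stepMembers[[s]] <- sort(c(get(a), get(b)))
    keep <- min(ia, ib); drop <- max(ia, ib)
    clusters[[keep]] <- stepMembers[[s]]
    alive[drop] <- FALSE
    slot[s] <- keep
    out[[s]] <- sort(vapply(clusters[alive],
                            function(cl) paste(cl, collapse = ","),
                            character(1)))
  }
  out
}

# random samples x variables matrix with fixed seed
randMatrix <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p)
}

# two-cultivar synthetic spec built from the reference table's CV1 means
nullTwoGroupSpec <- function(seed, cv = 0.05, n = 3) {
  m <- cultivarMeans(fixContents())
  base <- cbind(A = m[, "CV1"], B = m[, "CV1"])
  synthSpec(base, cv = cv, n_replicates = n, seed = seed)
}
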