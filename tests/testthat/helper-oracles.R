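## Toy criteria builders and independent brute-force oracles used across the
## suite. Oracles are deliberately naive (enumeration, O(n^2) pair counts)
## and share no code with the implementation they check.

toyWeighted <- function(weights = c(A = 4, B = 3.5), threshold = 7,
                        strict = TRUE, transform = NULL) {
  ## map toy item names onto arbitrary vocabulary features
  feats <- featureVocabulary()[seq_along(weights)]
  criteriaSetFromList(list(
    name = "toy-weighted", rule_kind = "weighted_sum_threshold",
    threshold = threshold, threshold_is_strict = strict,
    probability_transform = transform,
    items = Map(function(id, f, w)
      list(item_id = id, predicate = f, weight = w),
      names(weights), feats, weights)))
}

toyDomain <- function(itemWeights, domains, threshold = 10) {
  ## itemWeights: named numeric; domains: parallel character vector
  feats <- featureVocabulary()[seq_along(itemWeights)]
  criteriaSetFromList(list(
    name = "toy-domain", rule_kind = "domain_weighted_threshold",
    threshold = threshold, threshold_is_strict = FALSE,
    items = Map(function(id, f, w, d)
      list(item_id = id, predicate = f, weight = w, domain = d),
      names(itemWeights), feats, itemWeights, domains)))
}

## feature matrix (features x patients) for toy sets: row i of 'patterns' is
## one patient's 0/1 vector over the toy items in definition order
toyRecords <- function(criteria, patterns) {
  feats <- vapply(itemTable(criteria)$predicate, identity, character(1))
  m <- t(patterns)
  rownames(m) <- feats
  storage.mode(m) <- "integer"
  m
}

## brute-force domain-weighted score: per domain, max weight among satisfied
## items, summed over domains
oracleDomainScore <- function(weights, domains, pattern) {
  sum(vapply(unique(domains), function(d) {
    w <- weights[domains == d & pattern == 1]
    if (length(w)) max(w) else 0
  }, numeric(1)))
}

## O(n^2) concordant-pair AUC with half ties
oracleAUC <- function(scores, truth) {
  x <- scores[truth == 1]; y <- scores[truth == 0]
  conc <- 0
  for (xi in x) conc <- conc + sum(xi > y) + 0.5 * sum(xi == y)
  conc / (length(x) * length(y))
}

## exact two-sided Mann-Whitney p by full enumeration of group assignments
oracleMWPExact <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  uStat <- function(sel) {
    x <- pooled[sel]; y <- pooled[-sel]
    s <- 0
    for (xi in x) s <- s + sum(xi > y) + 0.5 * sum(xi == y)
    s
  }
  u0 <- uStat(seq_len(n1))
  us <- apply(idx, 2L, uStat)
  mu <- n1 * (length(pooled) - n1) / 2
  mean(abs(us - mu) >= abs(u0 - mu) - 1e-9)
}
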