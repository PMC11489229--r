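test_that("predicate language has standard boolean semantics with absent = 0", {
  rec <- c(leucopenia = 1, ana = 1, biopsy_proven_nephritis = 1,
           anti_dsdna = 1)
  expect_equal(
    evaluatePredicate("or(leucopenia, thrombocytopenia_aiha, anemia)", rec), 1L)
  expect_equal(evaluatePredicate("not(ana)", rec), 0L)
  ## nephritis=1, ana=0, anti_dsDNA=1
  rec2 <- c(biopsy_proven_nephritis = 1, ana = 0, anti_dsdna = 1)
  expect_equal(
    evaluatePredicate("and(biopsy_proven_nephritis, or(ana, anti_dsdna))",
                      rec2), 1L)
  ## absent features are 0; undeclared names are an error
  expect_equal(evaluatePredicate("anemia", c(ana = 1)), 0L)
  expect_error(evaluatePredicate("or(ana, XYZ)", rec), "undeclared")
  expect_error(evaluatePredicate("system('ls')", rec), "disallowed|parse")
})

test_that("predicate evaluation matches truth-table enumeration", {
  ## all 8 assignments of three features, several compound predicates
  preds <- c("and(ana, or(leucopenia, anemia))",
             "or(and(ana, leucopenia), not(anemia))",
             "not(or(ana, and(leucopenia, anemia)))")
  ref <- list(function(a, l, n) a & (l | n),
              function(a, l, n) (a & l) | !n,
              function(a, l, n) !(a | (l & n)))
  grid <- expand.grid(ana = 0:1, leucopenia = 0:1, anemia = 0:1)
  for (k in seq_along(preds)) {
    got <- apply(grid, 1L, function(r) evaluatePredicate(preds[k], r))
    want <- as.integer(mapply(ref[[k]], grid$ana == 1, grid$leucopenia == 1,
                              grid$anemia == 1))
    expect_equal(unname(got), want, info = preds[k])
  }
})

test_that("bundled SLERPI definition satisfies its published anchors", {
  s <- bundledCriteria("SLERPI")
  it <- itemTable(s)
  w <- it$weight
  expect_equal(sum(w[w > 0]), 30.5)
  expect_equal(sum(w < 0), 1L)
  expect_equal(it$weight[it$item_id == "ild"], -1)
  expect_equal(it$weight[it$item_id == "thrombocytopenia_aiha"], 4.5)
  expect_equal(nrow(it), 14L)
  thr <- decisionThreshold(s)
  expect_equal(unname(thr["threshold"]), 7)
  expect_equal(unname(thr["strict"]), 1)
})

test_that("criteria definition loading rejects invalid definitions", {
  expect_error(criteriaSetFromList(list(name = "x")), "lacks field")
  expect_error(criteriaSetFromList(list(
    name = "x", rule_kind = "weighted_sum_threshold", threshold = 1,
    items = list(list(item_id = "a", predicate = "XYZ", weight = 1)))),
    "undeclared feature")
  ## a definition calling itself SLERPI must honor the 30.5 anchor
  expect_error(criteriaSetFromList(list(
    name = "SLERPI", rule_kind = "weighted_sum_threshold", threshold = 7,
    threshold_is_strict = TRUE,
    items = list(list(item_id = "a", predicate = "ana", weight = 4)))),
    "30.5")
  ## minimal toy definition loads
  toy <- toyWeighted()
  expect_s4_class(toy, "CriteriaSet")
  expect_equal(nrow(itemTable(toy)), 2L)
})

test_that("weighted-sum scoring: strict threshold, ILD penalty, maximum", {
  s <- bundledCriteria("SLERPI")
  feats <- itemTable(s)$predicate
  none <- setNames(rep(0, 14), feats)
  r <- applyCriteria(none, s)
  expect_equal(r$score, 0)
  expect_equal(r$classified, 0L)
  ## only ILD present: score -1, not classified
  ildOnly <- none; ildOnly["ild"] <- 1
  r <- applyCriteria(ildOnly, s)
  expect_equal(r$score, -1)
  expect_equal(r$classified, 0L)
  ## all 13 positive features, no ILD: maximum score, classified
  maxRec <- setNames(rep(1, 14), feats); maxRec["ild"] <- 0
  r <- applyCriteria(maxRec, s)
  expect_equal(r$score, 30.5)
  expect_equal(r$classified, 1L)
  ## adding ILD to any record lowers the score by exactly 1
  withIld <- maxRec; withIld["ild"] <- 1
  expect_equal(applyCriteria(withIld, s)$score, 29.5)
})

test_that("toy weighted set: strict-threshold boundary behaviour", {
  toy <- toyWeighted(c(A = 4, B = 3.5), threshold = 7, strict = TRUE)
  m <- toyRecords(toy, rbind(c(1, 0), c(1, 1), c(0, 0)))
  r <- applyCriteria(m, toy)
  expect_equal(r$score, c(4, 7.5, 0))
  expect_equal(r$classified, c(0L, 1L, 0L))
  ## a patient scoring exactly the threshold is NOT classified under strict
  toy7 <- toyWeighted(c(A = 3, B = 4), threshold = 7, strict = TRUE)
  r7 <- applyCriteria(toyRecords(toy7, rbind(c(1, 1))), toy7)
  expect_equal(r7$score, 7)
  expect_equal(r7$classified, 0L)
  ## same score classifies under a non-strict threshold
  toy7n <- toyWeighted(c(A = 3, B = 4), threshold = 7, strict = FALSE)
  expect_equal(applyCriteria(toyRecords(toy7n, rbind(c(1, 1))), toy7n)$classified,
               1L)
})

test_that("adding a satisfied positive item never decreases any score", {
  ## property over random toy sets and random records, all three rule kinds
  set.seed(11)
  for (rep in 1:25) {
    k <- sample(3:8, 1)
    w <- round(runif(k, 0.5, 5), 1)
    names(w) <- paste0("i", seq_len(k))
    doms <- sample(paste0("d", 1:3), k, replace = TRUE)
    sets <- list(
      toyWeighted(w, threshold = 4),
      toyDomain(w, doms, threshold = 4))
    pattern <- rbinom(k, 1, 0.5)
    off <- which(pattern == 0)
    if (!length(off)) next
    add <- sample(off, 1)
    pattern2 <- pattern; pattern2[add] <- 1
    for (s in sets) {
      sc1 <- applyCriteria(toyRecords(s, rbind(pattern)), s)$score
      sc2 <- applyCriteria(toyRecords(s, rbind(pattern2)), s)$score
      expect_gte(sc2, sc1)
    }
  }
})

test_that("probability transform and ordinal categories work end to end", {
  toy <- toyWeighted(c(A = 4, B = 3.5), threshold = 7, strict = TRUE,
    transform = list(intercept = -3, coefficients = list(A = 4, B = 2)))
  m <- toyRecords(toy, rbind(c(0, 0), c(1, 0), c(1, 1)))
  r <- applyCriteria(m, toy)
  expect_equal(r$probability_pct, 100 * plogis(c(-3, 1, 3)))
  expect_equal(as.character(r$category), c("unlikely", "likely", "definite"))
})

test_that("probability categories partition [0,100] per the ordinal scale", {
  expect_equal(as.character(probabilityCategory(99.98)), "definite")
  expect_equal(as.character(probabilityCategory(2.12)), "unlikely")
  expect_equal(as.character(probabilityCategory(c(44, 14.999, 0, 15, 86.9, 87, 100))),
               c("likely", "unlikely", "unlikely", "possible", "likely",
                 "definite", "definite"))
  expect_error(probabilityCategory(-0.1), "\\[0, 100\\]")
  expect_error(probabilityCategory(100.1), "\\[0, 100\\]")
  ## totality: a fine grid maps to exactly one category each
  g <- seq(0, 100, by = 0.25)
  expect_false(anyNA(probabilityCategory(g)))
})

test_that("applyCriteria preserves order, ids and handles empty cohorts", {
  s <- bundledCriteria("SLERPI")
  empty <- matrix(integer(0), nrow = 14, ncol = 0,
                  dimnames = list(itemTable(s)$predicate, NULL))
  expect_equal(nrow(applyCriteria(empty, s)), 0L)
  coh <- generateCohort(defaultCohortSpec(), seed = 3)
  for (cs in bundledCriteria()) {
    r <- applyCriteria(coh, cs)
    expect_equal(nrow(r), 865L)
    expect_identical(r$patient_id, colnames(coh))
  }
})
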