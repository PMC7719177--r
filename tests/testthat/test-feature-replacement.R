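test_that("pair scores recover identity, anti-rank and degenerate columns", {
  x <- c(0, 1, 2, 3, 0, 1, 2, 3)
  expect_equal(pair_score(x, x, "correlation", min_overlap = 2), 1)
  expect_equal(pair_score(x, x, "nearest_neighbor", min_overlap = 2), 0)
  # MI of a column with itself is its entropy
  px <- table(x) / length(x)
  expect_equal(pair_score(x, x, "mutual_information", min_overlap = 2),
               -sum(px * log(px)))
  expect_equal(pair_score(0:3, 3:0, "correlation", min_overlap = 2), -1)
  expect_equal(pair_score(rep(2, 8), x, "mutual_information", min_overlap = 2), 0)
  # Spearman undefined for a constant column -> candidate skipped
  expect_true(is.na(pair_score(rep(2, 8), x, "correlation", min_overlap = 2)))
  # insufficient overlap -> NA
  expect_true(is.na(pair_score(c(1, NA, NA), c(1, 2, 3), "correlation",
                               min_overlap = 2)))
})

test_that("pair scores match independent formulations", {
  set.seed(40)
  for (i in 1:25) {
    x <- sample(0:4, 40, replace = TRUE)
    y <- pmin(4, pmax(0, x + sample(-1:1, 40, replace = TRUE)))
    expect_equal(pair_score(x, y, "correlation", min_overlap = 2),
                 cor(rank(x), rank(y)))
    expect_equal(pair_score(x, y, "nearest_neighbor", min_overlap = 2),
                 -sqrt(sum((x - y)^2)) / sqrt(length(x)))
    # MI = H(x) + H(y) - H(x, y)
    H <- function(v) { p <- table(v) / length(v); -sum(p * log(p)) }
    expect_equal(pair_score(x, y, "mutual_information", min_overlap = 2),
                 H(x) + H(y) - H(paste(x, y)), tolerance = 1e-12)
  }
})

test_that("an exact duplicate wins the general map under all three scores", {
  set.seed(8)
  a <- sample(0:4, 500, replace = TRUE)
  noisy <- pmin(4, pmax(0, a + sample(c(-1, 0, 0, 1), 500, replace = TRUE)))
  indep <- sample(0:4, 500, replace = TRUE)
  tab <- make_table(cbind(a = a, b = a, c = indep, d = noisy),
                    model_features = "a")
  for (m in c("correlation", "nearest_neighbor", "mutual_information")) {
    map <- build_general_map(tab, "a", m)
    expect_equal(map$targets$a$candidate[1], "b")
    # and the noisy copy outranks independent noise
    expect_lt(match("d", map$targets$a$candidate),
              match("c", map$targets$a$candidate))
  }
})

test_that("top-ranked candidate equals exhaustive argmax on random tables", {
  for (seed in 1:100) {
    tab <- rand_table(40, 5, miss = 0.1, seed = seed + 300)
    m <- c("correlation", "nearest_neighbor", "mutual_information")[
      seed %% 3 + 1]
    map <- build_general_map(tab, "f1", m, min_overlap = 10)
    cand <- setdiff(colnames(tab$values), "f1")
    s <- vapply(cand, function(g) pair_score(tab$values[, "f1"],
                                             tab$values[, g], m,
                                             min_overlap = 10), numeric(1))
    expect_equal(map$targets$f1$candidate[1], cand[which.max(s)])
    expect_equal(map$targets$f1$score, sort(s[!is.na(s)], decreasing = TRUE),
                 ignore_attr = TRUE)
  }
})

test_that("single-candidate pools and unmappable features behave", {
  tab <- rand_table(40, 2, miss = 0, seed = 5)
  map <- build_general_map(tab, "f1", "correlation", min_overlap = 10)
  expect_equal(map$targets$f1$candidate, "f2")
  short <- rand_table(10, 2, miss = 0, seed = 5)
  expect_error(build_general_map(short, "f1", "correlation", min_overlap = 30),
               "unmappable")
})

test_that("replacement copies the best observed candidate, then falls back", {
  tab <- rand_table(100, 4, miss = 0, seed = 2)
  map <- build_general_map(tab, "f1", "correlation", min_overlap = 10)
  top2 <- map$targets$f1$candidate[1:2]
  fb <- fit_univariate(tab, "mode", "f1")
  rec <- tab$values[1, ]
  rec["f1"] <- NA
  rec[top2[1]] <- 3
  out <- apply_replacement(rec, map, tab$features, "f1", fb)
  expect_equal(out[["f1"]], 3)
  rec[top2[1]] <- NA
  rec[top2[2]] <- 1
  out <- apply_replacement(rec, map, tab$features, "f1", fb)
  expect_equal(out[["f1"]], 1)
  rec[setdiff(names(rec), "f1")] <- NA
  out <- apply_replacement(rec, map, tab$features, "f1", fb)
  expect_equal(out[["f1"]], fb$constants[["f1"]])
  # nothing missing -> identity, and filled count == missing count
  full <- tab$values[2, ]
  expect_identical(apply_replacement(full, map, tab$features, "f1", fb), full)
})

test_that("replacement substitutes exactly the missing features, never more", {
  tab <- rand_table(200, 6, miss = 0.3, seed = 9)
  mf <- c("f1", "f2", "f3")
  map <- build_general_map(tab, mf, "correlation", min_overlap = 20)
  fb <- fit_univariate(tab, "mode", mf)
  out <- apply_replacement_table(tab, map, mf, fb)
  expect_equal(missing_count(out, mf), 0)
  n_filled <- sum(!is.na(out$values[, mf]) & is.na(tab$values[, mf]))
  expect_equal(n_filled, missing_count(tab, mf))
  # non-model features untouched
  expect_identical(out$values[, c("f4", "f5", "f6")],
                   tab$values[, c("f4", "f5", "f6")])
})

test_that("dynamic maps with k = |train| reproduce the general map bit-for-bit", {
  tab <- rand_table(120, 5, miss = 0.1, seed = 14)
  rec <- tab$values[1, ]
  for (m in c("correlation", "nearest_neighbor", "mutual_information")) {
    gmap <- build_general_map(tab, c("f1", "f2"), m, min_overlap = 20)
    dmap <- build_dynamic_map(rec, tab, c("f1", "f2"), m, k = 120,
                              min_overlap = 20)
    expect_identical(dmap$targets, gmap$targets)
  }
  # identical records -> identical maps
  d1 <- build_dynamic_map(rec, tab, "f1", "correlation", k = 60,
                          min_overlap = 20)
  d2 <- build_dynamic_map(rec, tab, "f1", "correlation", k = 60,
                          min_overlap = 20)
  expect_identical(d1$targets, d2$targets)
  expect_warning(build_dynamic_map(rec, tab, "f1", "correlation", k = 500,
                                   min_overlap = 20), "fewer than k")
})

test_that("dynamic maps adapt to the record's neighborhood", {
  # two regimes keyed by f4: among records like the test record (f4 = 0)
  # feature c copies a exactly, while globally b is the better match
  set.seed(77)
  n <- 400
  regime <- rep(c(0, 4), each = n / 2)
  a <- sample(0:4, n, replace = TRUE)
  b <- pmin(4, pmax(0, a + sample(c(-1, 0, 1), n, replace = TRUE)))
  cc <- ifelse(regime == 0, a, sample(0:4, n, replace = TRUE))
  tab <- make_table(cbind(a = a, b = b, c = cc, f4 = regime),
                    model_features = "a")
  rec <- c(a = NA, b = 2, c = 3, f4 = 0)
  dmap <- build_dynamic_map(rec, tab, "a", "correlation", k = n / 2,
                            min_overlap = 20)
  expect_equal(dmap$targets$a$candidate[1], "c")
  # brute-force check on the selected subset
  sub_idx <- which(regime == 0)
  s_c <- cor(rank(a[sub_idx]), rank(cc[sub_idx]))
  expect_equal(dmap$targets$a$score[1], s_c)
})
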