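test_that("mean resultant magnitude matches circular statistics", {
  expect_equal(mean_resultant(rep(1.2, 5)), 1)
  expect_equal(mean_resultant(c(0, pi)), 0, tolerance = 1e-12)
  expect_equal(mean_resultant(c(0, 0, pi)), 1 / 3, tolerance = 1e-12)
  expect_equal(mean_resultant(0.4), 1)  # singleton
  expect_error(mean_resultant(numeric(0)))
  set.seed(31)
  for (i in 1:50) {
    ang <- runif(sample(2:10, 1), -pi, pi)
    rb <- mean_resultant(ang)
    expect_true(rb >= 0 && rb <= 1 + 1e-12)
    # invariant under global rotation
    expect_equal(rb, mean_resultant(ang + runif(1, -10, 10)), tolerance = 1e-12)
  }
})

test_that("fuzzy clusters grow greedily and merge duplicates", {
  # fully synchronized channels collapse to one all-channel cluster
  fc <- create_fuzzy_clusters(rep(0.3, 8), r = 0.5)
  expect_equal(nrow(fc), 1L)
  expect_equal(sort(fc$members[[1]]), 1:8)
  expect_equal(fc$rbar, 1)
  # two rigid groups at offset pi stay separate at r = 0.9
  ph <- c(rep(0, 4), rep(pi, 4))
  fc2 <- create_fuzzy_clusters(ph, r = 0.9)
  expect_equal(nrow(fc2), 2L)
  keys <- sapply(lapply(fc2$members, sort), paste, collapse = ",")
  expect_setequal(keys, c("1,2,3,4", "5,6,7,8"))
  # every emitted cluster satisfies rbar >= r
  expect_true(all(fc2$rbar >= 0.9))
  expect_error(create_fuzzy_clusters(ph, r = 1.2))
})

test_that("implementation agrees with the naive R oracle on random draws", {
  set.seed(41)
  for (i in 1:60) {
    n <- sample(3:9, 1)
    ph <- runif(n, -pi, pi)
    r <- runif(1, 0.5, 0.98)
    fc <- create_fuzzy_clusters(ph, r)
    sets_pkg <- lapply(fc$members, sort)
    sets_or <- oracle_fuzzy(ph, r)
    expect_setequal(sapply(sets_pkg, paste, collapse = ","),
                    sapply(sets_or, paste, collapse = ","))
    hp <- convert_to_hard(fc, ph, r)
    hp_or <- oracle_hard(sets_or, ph, r)
    expect_setequal(sapply(lapply(hp$members, sort), paste, collapse = ","),
                    sapply(lapply(hp_or, sort), paste, collapse = ","))
  }
})

test_that("hard conversion resolves overlaps by rbar priority", {
  # three channels, fuzzy {1,2} and {2,3}; {1,2} is tighter
  ph <- c(0, 0.2, 0.9)
  fc <- tibble::tibble(members = list(c(1L, 2L), c(2L, 3L)),
                       rbar = c(mean_resultant(ph[1:2]), mean_resultant(ph[2:3])))
  hp <- convert_to_hard(fc, ph, r = 0.9)
  sets <- sapply(lapply(hp$members, sort), paste, collapse = ",")
  expect_setequal(sets, c("1,2", "3"))
  # no overlap to resolve
  hp2 <- convert_to_hard(tibble::tibble(members = list(1:3), rbar = 1),
                         rep(0, 3), r = 0.9)
  expect_equal(hp2$members, list(1:3))
})

test_that("hard partitions are disjoint and covering for random inputs", {
  set.seed(51)
  for (i in 1:300) {
    n <- sample(3:10, 1)
    ph <- runif(n, -pi, pi)
    r <- runif(1, 0.3, 0.99)
    hp <- convert_to_hard(create_fuzzy_clusters(ph, r), ph, r)
    all_members <- unlist(hp$members)
    expect_equal(sort(all_members), 1:n)   # covering, no duplicates
    multi <- lengths(hp$members) > 1
    if (any(multi)) expect_true(all(hp$rbar[multi] >= r))
    expect_true(all(hp$rbar >= 0 & hp$rbar <= 1 + 1e-12))
  }
})

test_that("uniform phases at a strict threshold yield mostly singletons", {
  # frozen from the independent oracle: with 8 i.i.d. uniform phases and
  # r = 0.99 the expected singleton fraction is ~2/3 (a pair joins when
  # two phases fall within 2*acos(0.99) = 16.3 degrees)
  set.seed(7)
  fr <- replicate(300, {
    ph <- runif(8, -pi, pi)
    mean(lengths(create_fuzzy_clusters(ph, 0.99)$members) == 1)
  })
  expect_equal(mean(fr), 0.67, tolerance = 0.05)
})

test_that("cluster series labels every cell with a valid partition", {
  fs <- 128
  g <- center_frequencies(2, 8, 3)
  n <- seq_len(6 * fs)
  x <- matrix(rep(sin(2 * pi * 4 * n / fs), 4), 4, byrow = TRUE)
  ph <- instantaneous_phase(analytic_decompose(x, grid = g, fs = fs))
  ce <- cluster_series(ph, r = 0.9)
  interior <- which(!attr(ph, "coi")[, 2])
  # identical sinusoids: one all-channel cluster at every interior sample
  expect_true(all(ce[, interior, 2] == strtoi("F", 16L)))
  # random tensor: partition validity at every cell
  set.seed(61)
  tens <- array(runif(5 * 40 * 2, -pi, pi), dim = c(5, 40, 2))
  ce2 <- cluster_series(tens, r = 0.8)
  for (k in 1:2) for (s in c(1, 20, 40)) {
    codes <- ce2[, s, k]
    # each channel's own bit must be set in its cluster code
    bits <- 8 - seq_len(5)
    expect_true(all(bitwAnd(codes, 2^bits) > 0))
    # channels sharing a code form the exact member set of that code
    for (cd in unique(codes)) {
      members <- which(codes == cd)
      expect_equal(sum(2^(8 - members)), cd)
    }
  }
})

test_that("cluster series equals the per-cell R composition and is equivariant", {
  set.seed(71)
  tens <- array(runif(4 * 15, -pi, pi), dim = c(4, 15, 1))
  ce <- cluster_series(tens, r = 0.85)
  for (s in seq_len(15)) {
    ph <- tens[, s, 1]
    hp <- oracle_hard(oracle_fuzzy(ph, 0.85), ph, 0.85)
    codes <- integer(4)
    for (cl in hp) codes[cl] <- sum(2^(4 - cl))
    expect_equal(as.integer(ce[, s, 1]), codes)
  }
  # permuting channels permutes memberships
  perm <- c(3, 1, 4, 2)
  ce_p <- cluster_series(tens[perm, , , drop = FALSE], r = 0.85)
  for (s in seq_len(15)) {
    orig_sets <- lapply(unique(ce[, s, 1]), function(cd) which(ce[, s, 1] == cd))
    perm_sets <- lapply(unique(ce_p[, s, 1]), function(cd) which(ce_p[, s, 1] == cd))
    mapped <- lapply(orig_sets, function(st) sort(match(st, perm)))
    expect_setequal(sapply(lapply(perm_sets, sort), paste, collapse = ","),
                    sapply(mapped, paste, collapse = ","))
  }
})

test_that("mCPS recovers unambiguous planted partitions (exhaustive oracle)", {
  set.seed(81)
  for (i in 1:20) {
    n <- sample(4:6, 1)
    k1 <- sample(2:(n - 2), 1)
    offset <- runif(1, pi / 2 + 0.2, pi)
    base <- runif(1, -pi, pi)
    ph <- c(rep(base, k1), rep(base + offset, n - k1))
    ph <- ((ph + pi) %% (2 * pi)) - pi
    r <- 0.9
    # oracle: feasible partitions (every multi-channel block rbar >= r)
    # with the fewest blocks; must be unique here
    parts <- oracle_partitions(n)
    feasible <- Filter(function(p) {
      all(sapply(p, function(b) length(b) == 1 || oracle_rbar(ph[b]) >= r))
    }, parts)
    sizes <- sapply(feasible, length)
    best <- feasible[sizes == min(sizes)]
    expect_length(best, 1L)
    key <- function(p) paste(sort(sapply(p, function(b) paste(sort(b), collapse = ","))),
                             collapse = ";")
    hp <- convert_to_hard(create_fuzzy_clusters(ph, r), ph, r)
    expect_equal(key(hp$members), key(best[[1]]))
  }
})
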