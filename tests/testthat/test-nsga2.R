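test_that("Pareto dominance follows the componentwise definition", {
  expect_false(dominates(c(3, 2), c(3, 2)))   # no strict improvement
  expect_true(dominates(c(3, 1), c(4, 2)))
  expect_false(dominates(c(3, 5), c(4, 1)))   # incomparable
  expect_true(dominates(c(3, 1), c(3, 2)))    # equal on one, better on one
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "length")
})

test_that("non-dominated sorting matches a brute-force scan", {
  expect_identical(nondominated_sort(matrix(c(1, 2), 1)), list(1L))
  two <- rbind(c(1, 1), c(2, 2))
  expect_identical(front_sets(nondominated_sort(two)), list(1L, 2L))
  set.seed(3)
  for (i in 1:30) {
    P <- sample(5:30, 1)
    O <- sample(2:4, 1)
    obj <- matrix(sample(0:5, P * O, replace = TRUE), P, O)  # many ties
    expect_identical(front_sets(nondominated_sort(obj)),
                     front_sets(brute_fronts(obj)))
  }
  expect_error(nondominated_sort(matrix(numeric(0), 0, 2)), "empty")
})

test_that("crowding distance rewards boundary and sparse individuals", {
  expect_identical(crowding_distance(rbind(c(1, 2))), Inf)
  expect_identical(crowding_distance(rbind(c(1, 2), c(3, 1))), c(Inf, Inf))
  # three collinear equally spaced points: middle scores 1 per objective
  tri <- rbind(c(0, 2), c(1, 1), c(2, 0))
  expect_identical(crowding_distance(tri), c(Inf, 2, Inf))
  # order invariance (distinct values)
  set.seed(4)
  obj <- matrix(runif(15), 5, 3)
  d <- crowding_distance(obj)
  perm <- sample(5)
  expect_equal(crowding_distance(obj[perm, ]), d[perm])
  # a degenerate zero-range objective contributes nothing
  flat <- cbind(c(0, 1, 2), c(5, 5, 5))
  expect_identical(crowding_distance(flat), c(Inf, 1, Inf))
})

test_that("offspring respect operator probabilities and the montage mask", {
  set.seed(5)
  P <- 20; C <- 12
  proxies <- matrix(runif(P * C), P, C)
  obj <- cbind(rowSums(proxies >= 0.5), runif(P))
  rk <- eegselect:::rank_population(obj)
  # pc = 0, pm = 0: children are verbatim copies of tournament winners
  cfg0 <- ga_config(pop_size = P, pc = 0, pm = 0)
  kids <- make_offspring(proxies, rk$rank, rk$crowding, cfg0)
  parent_keys <- apply(proxies, 1, paste, collapse = ",")
  kid_keys <- apply(kids, 1, paste, collapse = ",")
  expect_true(all(kid_keys %in% parent_keys))
  # identical parents, pm = 0: SBX of equal values returns the value
  same <- matrix(0.7, P, C)
  cfgx <- ga_config(pop_size = P, pc = 1, pm = 0)
  expect_equal(make_offspring(same, rk$rank, rk$crowding, cfgx), same)
  # masked genes are clamped in every child
  mask <- rep(c(TRUE, FALSE), length.out = C)
  cfg <- ga_config(pop_size = P, seed = 1)
  kids <- make_offspring(proxies, rk$rank, rk$crowding, cfg, mask)
  expect_true(all(kids[, !mask] == 0))
})

test_that("polynomial mutation flips bits at the analytically expected rate", {
  # oracle: for a proxy at distance t from the 0.5 threshold the mutation
  # kernel crosses it with probability 0.5 * (1 - t)^(eta + 1); averaged over
  # uniform proxies the per-mutated-gene flip probability is
  # (1 - 0.5^(eta+2)) / (eta + 2)
  eta <- 20
  C <- 10
  pm <- 1 / C
  p_flip <- (1 - 0.5^(eta + 2)) / (eta + 2)
  expected <- C * pm * p_flip            # flips per chromosome
  set.seed(6)
  n <- 10000
  X <- matrix(runif(n * C), n, C)
  Y <- eegselect:::poly_mutate(X, pm, eta)
  flips <- rowSums((X >= 0.5) != (Y >= 0.5))
  se <- sd(flips) / sqrt(n)
  expect_lt(abs(mean(flips) - expected), 3 * se + 1e-12)
})

test_that("evolution is deterministic, elitist, and mask-respecting", {
  mock_eval <- function(b) c(sum(b), abs(sum(b) - 4) + sum(which(b)) / 100)
  cfg <- ga_config(pop_size = 20, generations = 15, seed = 11)
  r1 <- evolve(mock_eval, n_genes = 10, config = cfg)
  r2 <- evolve(mock_eval, n_genes = 10, config = cfg)
  expect_identical(r1$log, r2$log)
  expect_identical(sum(r1$log$generation > 0), 20L * 15L)
  # per-objective population minima never increase across generations
  expect_true(all(diff(r1$pop_min[, 1]) <= 0))
  expect_true(all(diff(r1$pop_min[, 2]) <= 0))
  # montage mask honored in every logged chromosome
  mask <- c(rep(TRUE, 6), rep(FALSE, 4))
  rm_ <- evolve(mock_eval, n_genes = 10, config = cfg, mask = mask)
  bits <- do.call(rbind, lapply(rm_$log$bitstring, eegselect:::string_to_bits))
  expect_true(all(!bits[, 7:10]))
  # evaluation failures abort with the offending chromosome named
  bad_eval <- function(b) stop("boom")
  expect_error(evolve(bad_eval, n_genes = 3,
                      config = ga_config(pop_size = 4, generations = 2, seed = 2)),
               "chromosome")
})

test_that("elitism keeps surviving rank-1 objectives reachable", {
  # population minima per objective at generation g equal the minima over all
  # candidates seen so far (merged-population elitism with boundary crowding)
  mock_eval <- function(b) c(sum(b), sum(b * seq_along(b)) %% 7 + sum(b) / 10)
  cfg <- ga_config(pop_size = 16, generations = 20, seed = 3)
  res <- evolve(mock_eval, n_genes = 8, config = cfg)
  seen_min <- min(res$log$obj_2)
  expect_equal(min(res$final_obj[, 2]), seen_min)
})
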