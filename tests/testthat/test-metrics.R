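test_that("pairwise distances follow the canonical order", {
  s <- sort_record("p", "demo", c("a", "b"), c(0, 3), c(0, 4))
  expect_equal(pairwise_distances(s)$d, 5)

  its <- default_item_set()
  s20 <- simulate_sort(its$item_ids, its$category_of,
                       sorter_config("random_uniform", seed = 1))
  expect_length(pairwise_distances(s20)$d, 190)

  # hand-computed distances of the 4-item fixture, in canonical pair order
  dv <- pairwise_distances(fixture_sort_1())
  expect_equal(dv$pair_i, c("A1", "A1", "A1", "A2", "A2", "B1"))
  expect_equal(dv$pair_j, c("A2", "B1", "B2", "B1", "B2", "B2"))
  expect_equal(dv$d, c(1, 10, sqrt(101), sqrt(101), 10, 1))

  expect_error(pairwise_distances(
    sort_record("p", "demo", "only", 1, 1)), "2 items")
})

test_that("categoricality matches the hand-computed fixture and its invariances", {
  cof <- fixture_category_of()
  cs <- categoricality(fixture_sort_1(), cof)
  expect_equal(cs$mean_within, 1)
  expect_equal(cs$mean_between, (20 + 2 * sqrt(101)) / 4)
  expect_equal(cs$score, log((20 + 2 * sqrt(101)) / 4))  # ~ 2.305

  # 4x3 rectangle with categories on opposite horizontal edges: within
  # distances 4 and 4, between distances 3, 5, 5, 3 -> both means 4, score 0
  sq <- sort_record("sq", "demo", c("A1", "A2", "B1", "B2"),
                    x = c(0, 4, 0, 4), y = c(0, 0, 3, 3))
  expect_equal(categoricality(sq, cof)$score, 0)

  # invariant under uniform scaling and rigid motion
  for (tr in list(list(scale = 2), list(angle = 0.7, dx = 3, dy = 5),
                  list(angle = 2.1, scale = 0.3, reflect = TRUE))) {
    s2 <- do.call(transform_sort, c(list(fixture_sort_1()), tr))
    expect_equal(categoricality(s2, cof)$score, cs$score, tolerance = 1e-10)
  }

  coincident <- sort_record("c", "demo", c("A1", "A2", "B1", "B2"),
                            x = c(1, 1, 1, 1), y = c(2, 2, 2, 2))
  expect_error(categoricality(coincident, cof), "coincide")
})

test_that("alignment agrees with the rank-correlation oracle on the fixtures", {
  d1 <- pairwise_distances(fixture_sort_1())
  d2 <- pairwise_distances(fixture_sort_2())
  al <- alignment(d1, d2)
  expect_equal(unname(al["rho"]), oracle_spearman(d1$d, d2$d), tolerance = 1e-12)
  expect_equal(unname(al["rho"]), 7 / sqrt(272))  # hand computation, ~0.4244
  expect_equal(unname(al["z"]), atanh(7 / sqrt(272)))

  # symmetric, and at the clip for identical sorts
  expect_equal(alignment(d2, d1), al)
  self <- alignment(d1, d1)
  expect_equal(unname(self["rho"]), 1)
  expect_equal(unname(self["z"]), atanh(1 - 1e-6))

  mism <- pairwise_distances(sort_record("q", "demo", c("A1", "A2", "B1", "Bx"),
                                         1:4, 4:1))
  expect_error(alignment(d1, mism), "item set")
  flat <- pairwise_distances(sort_record("f", "demo", c("A1", "A2", "B1", "B2"),
                                         c(0, 1, 2, 3), c(0, 0, 0, 0)))
  # equally spaced collinear items: distances vary, fine; a truly flat vector:
  zerovar <- flat; zerovar$d <- rep(2, 6)
  expect_error(alignment(d1, zerovar), "zero variance")
})

test_that("alignment is invariant under rigid motion and scaling of either sort", {
  its <- default_item_set()
  s1 <- simulate_sort(its$item_ids, its$category_of,
                      sorter_config("categorical", seed = 21))
  s2 <- simulate_sort(its$item_ids, its$category_of,
                      sorter_config("categorical", seed = 22))
  base <- alignment(pairwise_distances(s1), pairwise_distances(s2))
  set.seed(99)
  for (i in 1:5) {
    t1 <- transform_sort(s1, angle = runif(1, 0, 2 * pi), scale = runif(1, 0.2, 3),
                         dx = runif(1, 0, 50), dy = runif(1, 0, 50),
                         reflect = i %% 2 == 0)
    t2 <- transform_sort(s2, angle = runif(1, 0, 2 * pi), scale = runif(1, 0.2, 3))
    moved <- alignment(pairwise_distances(t1), pairwise_distances(t2))
    expect_equal(moved, base, tolerance = 1e-9)
  }
})

test_that("subset alignment keeps the right pairs", {
  its <- default_item_set()
  s1 <- simulate_sort(its$item_ids, its$category_of,
                      sorter_config("random_uniform", seed = 5), "p1")
  s2 <- simulate_sort(its$item_ids, its$category_of,
                      sorter_config("random_uniform", seed = 6), "p2")
  d1 <- pairwise_distances(s1); d2 <- pairwise_distances(s2)
  w <- unname(its$category_of[d1$pair_i] == its$category_of[d1$pair_j])
  expect_equal(sum(w), 90)
  expect_equal(sum(!w), 100)
  ww <- subset_alignment(d1, d2, "within_category", its$category_of)
  bb <- subset_alignment(d1, d2, "between_category", its$category_of)
  expect_equal(unname(ww["rho"]), oracle_spearman(d1$d[w], d2$d[w]), tolerance = 1e-12)
  expect_equal(unname(bb["rho"]), oracle_spearman(d1$d[!w], d2$d[!w]), tolerance = 1e-12)
  same <- subset_alignment(d1, d1, "within_category", its$category_of)
  expect_equal(unname(same["rho"]), 1)
})

test_that("cohort alignment aggregates dyads within condition", {
  its <- default_item_set()
  g <- lapply(1:3, function(i)
    simulate_sort(its$item_ids, its$category_of, sorter_config("grid", seed = 4),
                  participant_id = paste0("g", i), condition = "grid"))
  am <- alignment_matrix(g)
  expect_equal(nrow(am$dyads), 3)
  expect_true(all(am$dyads$z == atanh(1 - 1e-6)))
  expect_true(all(am$participants$mean_alignment == atanh(1 - 1e-6)))

  # dyad counting across two conditions: n(n-1)/2 per condition
  coh <- simulate_cohort(n_per_condition = 7, seed = 2)
  am2 <- alignment_matrix(coh)
  expect_equal(nrow(am2$dyads), 3 * choose(7, 2))
  expect_true(all(table(am2$dyads$condition) == choose(7, 2)))

  single <- c(g, list(simulate_sort(its$item_ids, its$category_of,
                                    sorter_config("grid", seed = 9),
                                    "solo", "lonely")))
  expect_error(alignment_matrix(single), "single participant")
})

test_that("mean alignment of i.i.d. random sorts concentrates at zero", {
  its <- default_item_set()
  coh <- lapply(1:200, function(i)
    simulate_sort(its$item_ids, its$category_of,
                  sorter_config("random_uniform", seed = 1000 + i),
                  participant_id = paste0("r", i), condition = "null"))
  am <- alignment_matrix(coh)
  expect_lt(abs(mean(am$participants$mean_alignment)), 0.01)
})

test_that("dyad bridging returns min, max and absolute difference", {
  b <- dyad_bridge(1, 0.4)
  expect_equal(b, c(min = 0.4, max = 1, absdiff = 0.6))
  expect_equal(dyad_bridge(0.4, 1), b)          # symmetric
  expect_equal(unname(dyad_bridge(0.7, 0.7)["absdiff"]), 0)
})

test_that("RT filter applies the 150 ms floor and the upper 2-SD rule", {
  expect_equal(rt_filter(rep(400, 5)), rep(400, 5))  # SD rule vacuous when equal
  expect_equal(rt_filter(c(100, 400)), 400)          # floor drops 100 ms
  expect_length(rt_filter(numeric(0)), 0)

  # 20-trial fixture; survivors frozen from an independent enumeration
  # (mean 569.5, SD 344.94 computed before exclusion; cutoff 1259.4 ms)
  rt <- c(120, 140, 300, 350, 400, 420, 450, 480, 500, 510,
          520, 540, 560, 580, 600, 620, 650, 700, 1450, 1500)
  kept <- rt_filter(rt)
  expect_equal(kept, c(300, 350, 400, 420, 450, 480, 500, 510, 520, 540,
                       560, 580, 600, 620, 650, 700))
})

test_that("participant exclusion rules fire with the right reasons", {
  its <- default_item_set()
  mk <- function(id, moved) {
    s <- simulate_sort(its$item_ids, its$category_of,
                       sorter_config("random_uniform", seed = 3), id, "c1")
    s$moved_all <- moved
    s
  }
  coh <- list(mk("ok", TRUE), mk("lazy", FALSE), mk("sloppy", TRUE),
              mk("distracted", TRUE), mk("edge", TRUE))
  logs <- data.frame(participant_id = c("ok", "sloppy", "distracted", "edge"),
                     accuracy = c(0.95, 0.79, 0.90, 0.81),
                     catch_correct = c(9, 9, 6, 7))
  pf <- participant_filter(coh, logs)
  expect_equal(pf$reason, c("ok", "sort-incomplete", "low-accuracy",
                            "failed-catch", "ok"))
  expect_equal(pf$kept, c(TRUE, FALSE, FALSE, FALSE, TRUE))
})
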