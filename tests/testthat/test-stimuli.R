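test_that("contour interpolation passes through the knots and closes", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  out <- interpolate_contour(sq, points_per_segment = 1)
  expect_equal(nrow(out), 5)
  expect_equal(out[1:4, ], sq, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(out[1, ], out[5, ], ignore_attr = TRUE)

  proto <- make_prototype("A", experiment = 1)
  cur <- interpolate_contour(proto$vertices, points_per_segment = 10)
  expect_equal(nrow(cur), 39 * 10 + 1)
  expect_equal(cur[1, ], cur[nrow(cur), ], ignore_attr = TRUE)
  knots <- cur[seq(1, nrow(cur) - 1, by = 10), ]
  expect_equal(knots, proto$vertices, ignore_attr = TRUE, tolerance = 1e-8)

  expect_error(interpolate_contour(cbind(c(0, 1, 0), c(0, 0, 1))), "4 vertices")
})

test_that("perturbation displaces only every fifth vertex, deterministically", {
  proto <- make_prototype("A")
  ex0 <- perturb_shape(proto, sd = 0, seed = 11)
  expect_equal(ex0$vertices, proto$vertices)

  ex1 <- perturb_shape(proto, sd = 0.25, seed = 11)
  ex1b <- perturb_shape(proto, sd = 0.25, seed = 11)
  expect_identical(ex1$vertices, ex1b$vertices)

  moved <- seq(1, 39, by = 5)
  expect_identical(ex1$vertices[-moved, ], proto$vertices[-moved, ])
  expect_true(all(ex1$vertices[moved, ] != proto$vertices[moved, ]))
  expect_error(perturb_shape(proto, sd = -1, seed = 1), "sd")
})

test_that("perturbation RMS displacement scales linearly with sd", {
  proto <- make_prototype("A")
  moved <- seq(1, 39, by = 5)
  rms <- function(sd) {
    vapply(1:100, function(s) {
      ex <- perturb_shape(proto, sd = sd, seed = s)
      sqrt(mean((ex$vertices[moved, ] - proto$vertices[moved, ])^2))
    }, 0)
  }
  ratio <- mean(rms(0.75)) / mean(rms(0.25))
  expect_gt(ratio, 2.6)   # expected 3 = 0.75/0.25 up to Monte-Carlo error
  expect_lt(ratio, 3.4)
})

test_that("category generation honours the per-level design", {
  protoA <- make_prototype("A", experiment = 1)
  ex1 <- generate_category(protoA, seed = 5)
  expect_length(ex1, 18)
  expect_equal(as.integer(table(vapply(ex1, `[[`, "", "distortion"))[c("high", "low", "medium")]),
               c(6L, 6L, 6L))
  expect_true(all(vapply(ex1, function(s) !is.null(s$contour), TRUE)))

  protoA2 <- make_prototype("A", experiment = 2)
  ex2 <- generate_category(protoA2, counts = c(fixed = 10), sds = c(fixed = 0.35),
                           seed = 5, contour = FALSE)
  expect_length(ex2, 10)
  expect_true(all(vapply(ex2, `[[`, "", "distortion") == "fixed"))
  expect_true(all(vapply(ex2, function(s) is.null(s$contour), TRUE)))

  expect_length(generate_category(protoA, counts = c(low = 0, medium = 0, high = 0),
                                  seed = 1), 0)
})

test_that("sort-set assembly gives 20 items with the 3+6+1 composition", {
  protoA <- make_prototype("A"); protoB <- make_prototype("B")
  catA <- c(generate_category(protoA, seed = 1), list(protoA))
  catB <- c(generate_category(protoB, seed = 2), list(protoB))
  seen <- c(sprintf("A_low_%02d", 1:3), sprintf("B_low_%02d", 1:3))
  set <- assemble_sort_set(catA, catB, seen)
  expect_length(set, 20)
  cats <- vapply(set, `[[`, "", "category")
  expect_equal(as.integer(table(cats)), c(10L, 10L))
  roles <- vapply(set, `[[`, "", "role")
  seen_flag <- vapply(set, `[[`, TRUE, "seen_in_preexposure")
  for (cc in c("A", "B")) {
    expect_equal(sum(roles == "prototype" & cats == cc), 1)
    expect_equal(sum(seen_flag & cats == cc), 3)
    expect_equal(sum(!seen_flag & roles == "exemplar" & cats == cc), 6)
  }
  # canonical ordering: A block before B block, each sorted by id
  ids <- vapply(set, `[[`, "", "shape_id")
  expect_equal(cats, rep(c("A", "B"), each = 10))
  expect_equal(ids[1:10], sort(ids[1:10]))

  expect_error(assemble_sort_set(catA, catB, c(seen, "nope")), "not found")
})

test_that("xAB trial lists pair every cross-category combination per block", {
  ids_a <- sprintf("A_%d", 1:9); ids_b <- sprintf("B_%d", 1:9)
  tr3 <- build_xab_trials(ids_a, ids_b, n_blocks = 3, seed = 7)
  expect_equal(nrow(tr3), 243)
  tr1 <- build_xab_trials(ids_a, ids_b, n_blocks = 1, seed = 7)
  expect_equal(nrow(tr1), 81)

  is_a <- function(x) x %in% ids_a
  expect_true(all(is_a(tr3$left_id) != is_a(tr3$right_id)))
  expect_true(all(tr3$sample_id == tr3$left_id | tr3$sample_id == tr3$right_id))
  for (blk in 1:3) {
    b <- tr3[tr3$block == blk, ]
    pair_key <- paste(ifelse(is_a(b$left_id), b$left_id, b$right_id),
                      ifelse(is_a(b$left_id), b$right_id, b$left_id))
    expect_equal(sort(pair_key), sort(paste(rep(ids_a, times = 9),
                                            rep(ids_b, each = 9))))
    counts <- table(b$correct_side)
    expect_lte(abs(diff(range(counts))), 1)
  }
  expect_identical(build_xab_trials(ids_a, ids_b, seed = 7), tr3)
  expect_error(build_xab_trials(ids_a, ids_b, prototype_ids = "A_1"),
               "prototype")
  expect_error(build_xab_trials(ids_a[1:8], ids_b), "exactly 9")
})

test_that("shapes round-trip through JSON", {
  proto <- make_prototype("B", experiment = 2)
  shapes <- c(list(proto), generate_category(proto, counts = c(fixed = 2),
                                             sds = c(fixed = 0.35), seed = 3,
                                             contour = FALSE))
  path <- withr::local_tempfile(fileext = ".json")
  write_shapes(shapes, path)
  back <- read_shapes(path)
  expect_equal(length(back), length(shapes))
  expect_equal(back[[1]]$vertices, shapes[[1]]$vertices)
  expect_equal(back[[2]]$shape_id, shapes[[2]]$shape_id)
  expect_null(back[[3]]$contour)
})
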