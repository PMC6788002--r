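test_that("age similarity is the min/max ratio", {
  expect_identical(fs_age(50, 50), 1)
  expect_identical(fs_age(30, 60), 0.5)
  expect_equal(fs_age(63, 57), 57 / 63)
  expect_identical(fs_age(30, 60), fs_age(60, 30))
  expect_error(fs_age(0, 10), "positive")
})

test_that("sex similarity is the matching indicator", {
  expect_identical(fs_sex("male", "male"), 1)
  expect_identical(fs_sex("male", "female"), 0)
  expect_identical(fs_sex("female", "female"), 1)
  expect_error(fs_sex("m", "male"), "male")
})

test_that("lab standardization fits on the pool and transfers to queries", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 20, 60))
  fit <- normalize_labs(m)
  expect_equal(colMeans(fit$labs), c(a = 0, b = 0))
  expect_equal(apply(fit$labs, 2, sd), c(a = 1, b = 1))
  # a test value equal to the training mean maps to 0
  q <- normalize_labs(cbind(a = 2, b = 30), fit$params)
  expect_equal(unname(q$labs[1, "a"]), 0)
  expect_equal(unname(q$labs[1, "b"]), 0)
  expect_error(normalize_labs(cbind(a = c(1, 1, 1))), "zero-variance.*a")
})

test_that("lab distance is Euclidean with strict length checks", {
  expect_identical(lab_distance(c(1, 2), c(1, 2)), 0)
  expect_identical(lab_distance(c(0, 0), c(3, 4)), 5)
  expect_identical(lab_distance(c(1, 5, 2), c(4, 1, 2)),
                   lab_distance(c(4, 1, 2), c(1, 5, 2)))
  expect_error(lab_distance(1:2, 1:3), "length")
})

test_that("batch lab similarity min-max normalizes per query", {
  pool <- rbind(c(0, 0), c(0.6, 0.8), c(1.2, 1.6))  # distances 0, 1, 2
  expect_equal(fs_lab_batch(c(0, 0), pool), c(1, 0.5, 0))
  expect_equal(fs_lab_batch(c(0, 0), rbind(c(0, 0), c(3, 4))), c(1, 0))
  expect_message(out <- fs_lab_batch(c(1, 1), rbind(c(1, 1), c(1, 1))),
                 "degenerate")
  expect_equal(out, c(1, 1))
})

test_that("diagnosis-set similarity reproduces hand-evaluated cases", {
  expect_identical(fs_d1("E109", "E109"), 1)
  expect_identical(fs_d1(c("E109", "I109"), c("I109", "E109")), 1)
  expect_identical(fs_d1("E109", "E119"), 0.5)  # 1 - (0.5 + 0.5)/2
  expect_identical(fs_d1("E109", "A011"), 0)    # cross-chapter, d = 1
  expect_error(fs_d1(character(0), "E109"), "non-empty")
})

test_that("diagnosis-set similarity agrees with the double-loop oracle", {
  set.seed(101)
  universe <- default_code_universe()$code
  for (i in 1:200) {
    X <- random_code_set(universe)
    Y <- random_code_set(universe)
    expect_equal(fs_d1(X, Y), oracle_fs_d1(X, Y), tolerance = 1e-12)
    expect_equal(fs_d1(X, Y), fs_d1(Y, X), tolerance = 1e-12)
  }
})

test_that("CCS cosine similarity handles identity, disjointness and zeros", {
  v <- function(idx) { out <- integer(259); out[idx] <- 1L; out }
  expect_equal(fs_d2(v(c(49, 101)), v(c(49, 101))), 1)
  expect_identical(fs_d2(v(49), v(101)), 0)
  expect_equal(fs_d2(v(c(49, 50)), v(c(49, 101))), 0.5)
  expect_warning(z <- fs_d2(v(integer(0)), v(49)), "all-zero")
  expect_identical(z, 0)
  expect_error(fs_d2(1:10, v(49)), "259")
})

test_that("patient similarity is a convex combination of the components", {
  w <- similarity_weights()
  expect_identical(patient_similarity(1, 1, 1, 1, w), 1)
  expect_identical(patient_similarity(0, 0, 0, 0, w), 0)
  expect_equal(patient_similarity(0.5, 0.5, 1, 1, w), 0.6)
  # monotone in each component, holding the others fixed
  base <- patient_similarity(0.3, 0.4, 0.5, 1, w)
  expect_gt(patient_similarity(0.5, 0.4, 0.5, 1, w), base)
  expect_gt(patient_similarity(0.3, 0.6, 0.5, 1, w), base)
  expect_gt(patient_similarity(0.3, 0.4, 0.7, 1, w), base)
  expect_error(patient_similarity(1.2, 0, 0, 0, w), "\\[0, 1\\]")
  expect_error(similarity_weights(0.5, 0.5, 0.5, 0.5), "sum to 1")
  expect_error(similarity_weights(1.5, -0.5, 0, 0), "\\[0, 1\\]")
})

test_that("similarity profiles match an independent hand computation", {
  x <- tiny_cohort()
  query <- x[1]
  pool <- x[2:6]
  m <- tiny_crosswalk()

  prof <- similarity_profile(query, pool, scheme = "icd", ccs_map = m)

  # spreadsheet-style recomputation from first principles
  mu <- colMeans(pool$labs)
  sd_ <- apply(pool$labs, 2, sd)
  zp <- sweep(sweep(pool$labs, 2, mu), 2, sd_, "/")
  zq <- (query$labs[1, ] - mu) / sd_
  d <- apply(zp, 1, function(r) sqrt(sum((r - zq)^2)))
  fsl <- 1 - (d - min(d)) / (max(d) - min(d))
  fsa <- pmin(query$age, pool$age) / pmax(query$age, pool$age)
  fss <- as.numeric(pool$sex == query$sex)
  fsd <- vapply(pool$diagnoses, function(dg)
    oracle_fs_d1(query$diagnoses[[1]], dg), numeric(1))
  ps <- 0.4 * fsd + 0.4 * fsl + 0.1 * fsa + 0.1 * fss
  expected <- ps[order(-ps, pool$id)]

  expect_equal(prof$ps, unname(expected), tolerance = 1e-12)
  expect_equal(prof$id, names(expected))
  expect_true(all(diff(prof$ps) <= 0))
  expect_true(all(prof$ps >= 0 & prof$ps <= 1))

  # CCS scheme: check the fs_d column against per-pair cosine
  prof2 <- similarity_profile(query, pool, scheme = "ccs", ccs_map = m)
  qv <- ccs_vector(query$diagnoses[[1]], m)
  fsd2 <- vapply(pool$diagnoses, function(dg)
    fs_d2(qv, ccs_vector(dg, m)), numeric(1))
  expect_equal(sort(prof2$fs_d, decreasing = TRUE),
               unname(sort(fsd2, decreasing = TRUE)), tolerance = 1e-12)
})

test_that("a pool patient identical to the query ranks first with PS 1", {
  x <- tiny_cohort()
  twin <- x[1]
  twin$id <- "t99"
  rownames(twin$labs) <- "t99"
  names(twin$diagnoses) <- "t99"
  pool <- x[2:6]
  pool2 <- cohort(c(pool$id, twin$id), c(pool$age, twin$age),
                  c(pool$sex, twin$sex), c(pool$diagnoses, twin$diagnoses),
                  rbind(pool$labs, twin$labs),
                  label = c(pool$label, twin$label))
  prof <- similarity_profile(x[1], pool2, scheme = "icd",
                             ccs_map = tiny_crosswalk())
  expect_equal(prof$id[1], "t99")
  expect_equal(prof$ps[1], 1)
})

test_that("single-patient pools give a length-1 profile in [0,1]", {
  x <- tiny_cohort()
  expect_message(
    prof <- similarity_profile(x[1], x[2], scheme = "icd",
                               ccs_map = tiny_crosswalk(),
                               lab_params = normalize_labs(x$labs)$params),
    NA)
  expect_equal(nrow(prof), 1L)
  expect_true(prof$ps >= 0 && prof$ps <= 1)
})

test_that("feature similarities are symmetric and bounded on random patients", {
  set.seed(7)
  x <- generate_cohort(synthetic_config(n_per_class = 15), seed = 11)
  params <- normalize_labs(x$labs)$params
  z <- normalize_labs(x$labs, params)$labs
  for (rep in 1:25) {
    i <- sample(cohort_size(x), 1); j <- sample(cohort_size(x), 1)
    a <- fs_age(x$age[i], x$age[j])
    s <- fs_sex(x$sex[i], x$sex[j])
    d1 <- fs_d1(x$diagnoses[[i]], x$diagnoses[[j]])
    d2 <- fs_d2(ccs_vector(x$diagnoses[[i]], default_ccs_map()),
                ccs_vector(x$diagnoses[[j]], default_ccs_map()))
    for (v in c(a, s, d1, d2)) expect_true(v >= 0 && v <= 1)
    expect_identical(d1, fs_d1(x$diagnoses[[j]], x$diagnoses[[i]]))
    expect_identical(lab_distance(z[i, ], z[j, ]), lab_distance(z[j, ], z[i, ]))
  }
})
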