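# Shared small study setup: generated cohort, screened features, pool
# standardization.
local_study <- function(n_per_class = 60, seed = 31) {
  x <- generate_cohort(synthetic_config(n_per_class = n_per_class),
                       seed = seed)
  split <- holdout_split(x, train_per_class = round(n_per_class * 2 / 3),
                         seed = seed)
  lab_params <- normalize_labs(split$train$labs)$params
  screened <- screen_diagnosis_features(split$train,
                                        exclude_prefixes = dm_code_prefixes())
  list(pool = split$train, test = split$test, lab_params = lab_params,
       screened = screened)
}

test_that("top-K selection respects ranking and the id tie-break", {
  st <- local_study()
  prof <- similarity_profile(st$test[1], st$pool,
                             lab_params = st$lab_params)
  expect_equal(select_top_k(prof, nrow(prof)), prof$id)
  expect_equal(select_top_k(prof, 1), prof$id[1])
  expect_error(select_top_k(prof, 0), "1\\.\\.")
  expect_error(select_top_k(prof, nrow(prof) + 1), "1\\.\\.")
  # ties broken by ascending id: construct a profile with known ties
  fake <- structure(
    data.frame(id = c("d", "b", "c", "a"), ps = c(0.9, 0.8, 0.8, 0.1)),
    class = c("similarity_profile", "data.frame"))
  fake <- fake[order(-fake$ps, fake$id), ]
  expect_equal(select_top_k(structure(fake,
    class = c("similarity_profile", "data.frame")), 3), c("d", "b", "c"))
})

test_that("random selection is seeded, uniform and without replacement", {
  ids <- sprintf("p%02d", 1:10)
  expect_identical(select_random(ids, 4, seed = 9),
                   select_random(ids, 4, seed = 9))
  full <- select_random(ids, 10, seed = 9)
  expect_setequal(full, ids)
  draws <- table(vapply(1:2000, function(i)
    select_random(ids, 1, seed = i), character(1)))
  expect_true(all(abs(draws / 2000 - 0.1) < 0.03))
  expect_error(select_random(ids, 11, seed = 1), "1\\.\\.")
})

test_that("feature vectors have the documented fixed layout", {
  st <- local_study(n_per_class = 25)
  fv <- build_feature_vectors(st$pool, screened = st$screened,
                              lab_params = st$lab_params)
  expect_equal(ncol(fv$x), 2 + length(st$screened) + 77)
  expect_equal(colnames(fv$x)[1:2], c("age", "sex_male"))
  expect_equal(rownames(fv$x), sort(st$pool$id))
  # hand-check one patient column by column
  pid <- st$pool$id[3]
  i <- st$pool$id == pid
  row <- fv$x[pid, ]
  expect_equal(unname(row["age"]), st$pool$age[i])
  expect_equal(unname(row["sex_male"]), as.numeric(st$pool$sex[i] == "male"))
  expect_equal(unname(row[st$screened]),
               as.numeric(st$screened %in% st$pool$diagnoses[[pid]]))
  expect_equal(unname(row[st$pool$lab_names]),
               unname((st$pool$labs[i, ] - st$lab_params$center) /
                        st$lab_params$scale))
  # patients with none of the screened codes get an all-zero block
  none <- cohort("q1", 50, "male", list("B181"),
                 st$pool$labs[1, , drop = FALSE])
  fvq <- build_feature_vectors(none, screened = st$screened,
                               lab_params = st$lab_params)
  expect_true(all(fvq$x[1, st$screened] == 0))
  # identical patients give identical rows
  expect_equal(unname(fv$x[pid, ]), unname(build_feature_vectors(
    st$pool, ids = pid, screened = st$screened,
    lab_params = st$lab_params)$x[1, ]))
})

test_that("kNN class probabilities match the full-sort oracle", {
  set.seed(55)
  for (rep in 1:10) {
    n <- 50
    x <- matrix(rnorm(n * 5), n, dimnames = list(sprintf("r%02d", 1:n)))
    y <- rbinom(n, 1, 0.5)
    q <- rnorm(5)
    k <- sample(c(1, 5, 25, 50), 1)
    expect_equal(knn_predict_proba(x, y, q, k), oracle_knn(x, y, q, k))
  }
  # 47 positives among k = 50 neighbors -> 0.94
  x <- matrix(seq_len(60), ncol = 1, dimnames = list(sprintf("r%02d", 1:60)))
  y <- c(rep(1, 47), rep(0, 13))
  expect_equal(knn_predict_proba(x, y, x[1, ], 50), 47 / 50)
  # a query equal to a training row with k = 1 returns that row's label
  expect_equal(knn_predict_proba(x, y, x[50, ], 1), y[50])
  # distance ties broken by ascending training row name
  xt <- matrix(c(0, 0, 0), ncol = 1, dimnames = list(c("b", "a", "c")))
  expect_equal(knn_predict_proba(xt, c(1, 0, 1), 0, 1), 0)  # "a" wins
  expect_error(knn_predict_proba(xt, c(1, 0, 1), 0, 4), "1\\.\\.")
})

test_that("kNN agrees with class::knn on random instances", {
  skip_if_not_installed("class")
  set.seed(77)
  n <- 40
  x <- matrix(rnorm(n * 4), n, dimnames = list(sprintf("r%02d", 1:n)))
  y <- rbinom(n, 1, 0.5)
  q <- matrix(rnorm(10 * 4), 10)
  for (k in c(1, 7, 15)) {
    ours <- knn_predict_proba(x, y, q, k)
    ref <- class::knn(x, q, factor(y), k = k, prob = TRUE, use.all = FALSE)
    ref_p1 <- ifelse(ref == "1", attr(ref, "prob"), 1 - attr(ref, "prob"))
    expect_equal(ours, ref_p1, tolerance = 1e-12)
  }
})

test_that("classifiers fit, score in [0,1], and are seed-deterministic", {
  st <- local_study(n_per_class = 40)
  fv <- build_feature_vectors(st$pool, screened = st$screened,
                              lab_params = st$lab_params)
  tv <- build_feature_vectors(st$test, screened = st$screened,
                              lab_params = st$lab_params)
  for (alg in c("knn", "lr", "rf")) {
    fit <- train_model(fv$x, fv$y, model_spec(alg), seed = 42)
    p <- predict(fit, tv$x)
    expect_length(p, cohort_size(st$test))
    expect_true(all(p >= 0 & p <= 1))
  }
  # RF identical under the same seed
  p1 <- predict(train_model(fv$x, fv$y, model_spec("rf"), seed = 1), tv$x)
  p2 <- predict(train_model(fv$x, fv$y, model_spec("rf"), seed = 1), tv$x)
  expect_identical(p1, p2)
  expect_error(train_model(fv$x, rep(1, nrow(fv$x)), model_spec("lr")),
               "single class")
})

test_that("LR separates a linearly separable toy problem", {
  x <- cbind(f1 = c(-3, -2, -1, 1, 2, 3), f2 = rnorm(6))
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- train_model(x, y, model_spec("lr"))
  expect_equal(as.numeric(predict(fit, x) > 0.5), y)
})

test_that("RF recovers a perfect single-feature signal", {
  set.seed(12)
  n <- 120
  x <- cbind(signal = c(rnorm(n / 2, 3), rnorm(n / 2, -3)),
             noise = rnorm(n))
  y <- rep(c(1, 0), each = n / 2)
  idx <- sample(n, 80)
  fit <- train_model(x[idx, ], y[idx], model_spec("rf"), seed = 3)
  expect_equal(auc(y[-idx], predict(fit, x[-idx, ])), 1)
})

test_that("personalized prediction composes the pipeline deterministically", {
  st <- local_study(n_per_class = 40)
  q <- st$test[1]
  p1 <- personalized_predict(q, st$pool, k = 25, model_spec("rf"),
                             screened = st$screened,
                             lab_params = st$lab_params, seed = 5)
  p2 <- personalized_predict(q, st$pool, k = 25, model_spec("rf"),
                             screened = st$screened,
                             lab_params = st$lab_params, seed = 5)
  expect_identical(p1, p2)
  expect_true(p1 >= 0 && p1 <= 1)
  # a pure top-K neighborhood falls back to the class proportion
  expect_message(
    pp <- personalized_predict(q, st$pool, k = 2, model_spec("lr"),
                               screened = st$screened,
                               lab_params = st$lab_params),
    "single-class", all = FALSE)
  expect_true(pp %in% c(0, 1))
})

test_that("on a pure informative neighborhood the prediction is correct-sided", {
  st <- local_study(n_per_class = 60, seed = 13)
  # pick a DM test patient; its top-similar pool is DM-enriched
  q <- st$test[which(st$test$label == 1)[1]]
  p <- suppressMessages(personalized_predict(
    q, st$pool, k = 30, model_spec("rf"), screened = st$screened,
    lab_params = st$lab_params, seed = 8))
  expect_gt(p, 0.5)
})
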