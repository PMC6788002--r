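# Shared fixtures and independent oracles, built in code at test time.

tiny_crosswalk <- function() {
  ccs_map(prefix = c("E1", "E110", "E112", "I10", "I25", "J45"),
          ccs = c(49, 50, 50, 99, 101, 128))
}

# Six hand-built patients with a 3-item lab panel.
tiny_cohort <- function() {
  cohort(
    id = sprintf("t%02d", 1:6),
    age = c(60, 55, 70, 40, 62, 58),
    sex = c("male", "male", "female", "female", "male", "female"),
    diagnoses = list(c("E109", "I109"), c("E119", "I251"),
                     c("I109", "I251"), "J459", c("E109", "E112"),
                     c("I109", "J459")),
    labs = matrix(c(5.2, 4.8, 6.1, 5.0, 7.3, 4.5,
                    1.1, 0.9, 1.4, 1.0, 1.6, 0.8,
                    140, 138, 145, 139, 150, 137),
                  nrow = 6, dimnames = list(NULL, c("glu", "crea", "na"))),
    label = c(1, 1, 0, 0, 1, 0))
}

# --- independent oracles -------------------------------------------------

# common-prefix hierarchical code similarity, character by character
oracle_code_sim <- function(a, b) {
  n <- 0
  for (k in seq_len(min(nchar(a), nchar(b)))) {
    if (substr(a, 1, k) == substr(b, 1, k)) n <- k else break
  }
  n / 4
}

# naive double-loop translation of the diagnosis-set similarity
oracle_fs_d1 <- function(X, Y) {
  X <- unique(X); Y <- unique(Y)
  d <- function(a, b) 1 - oracle_code_sim(a, b)
  t1 <- 0
  for (a in setdiff(X, Y)) {
    s <- 0
    for (b in Y) s <- s + d(a, b)
    t1 <- t1 + s / length(Y)
  }
  t2 <- 0
  for (b in setdiff(Y, X)) {
    s <- 0
    for (a in X) s <- s + d(b, a)
    t2 <- t2 + s / length(X)
  }
  1 - (t1 + t2) / length(unique(c(X, Y)))
}

# O(n^2) concordant-pair AUC with half credit for ties
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# full-sort nearest-neighbor class proportion, ties by row name
oracle_knn <- function(train_x, train_y, query, k) {
  d <- apply(train_x, 1, function(r) sqrt(sum((r - query)^2)))
  ord <- order(d, rownames(train_x))
  mean(train_y[ord[seq_len(k)]])
}

random_code_set <- function(universe, max_size = 6) {
  sample(universe, sample.int(max_size, 1))
}
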