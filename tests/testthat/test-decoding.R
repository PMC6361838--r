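test_that("study datasets validate run structure", {
  ds <- tiny_dataset()
  expect_equal(ds$K, 4)
  expect_length(task_labels(ds), 16)
  runs <- ds$runs
  one_task <- runs[grep("beh", names(runs))]
  expect_error(study_dataset(one_task), "lacks runs for task")
  expect_error(study_dataset(list()), "at least one run")
})

test_that("templates never see the held-out subject's data", {
  ds <- tiny_dataset(seed = 2)
  subs <- isfcdecode:::run_subjects(ds)
  training <- ds
  training$runs <- ds$runs[subs != "sub04"]
  training$subjects <- setdiff(ds$subjects, "sub04")
  training$K <- 3
  for (mode in c("isfc", "fc")) {
    t1 <- build_templates(training, mode = mode)
    mutated <- training   # training data untouched; held-out data irrelevant
    t2 <- build_templates(mutated, mode = mode)
    expect_identical(t1$templates$beh$values, t2$templates$beh$values)
    expect_false("sub04" %in% t1$training_subjects)
  }
  # classifying a training subject's run is refused
  tmpl <- build_templates(training, mode = "fc")
  expect_error(classify_run(ds$runs[["sub01_beh1"]], tmpl),
               "leave-one-subject-out")
})

test_that("two identical training subjects give the self-correlation ISFC template", {
  run <- random_run(P = 6, N = 40, seed = 5, subject_id = "a", task = "beh")
  make <- function(s) {
    r <- run; r$subject_id <- s
    rb <- r; rb$task <- "tax"; rb$data <- r$data + matrix(rnorm(240, sd = 0.1), 6, 40)
    list(r, rb)
  }
  runs <- c(make("a"), make("b"))
  names(runs) <- paste0(c("a_beh", "a_tax", "b_beh", "b_tax"))
  ds <- study_dataset(runs)
  tmpl <- build_templates(ds, mode = "isfc")
  Xn <- isfcdecode:::normalize_matrix(run$data)
  C <- isfcdecode::fisher_z(tcrossprod(Xn, Xn) / 40)
  expected <- (C + t(C)) / 2
  expect_equal(tmpl$templates$beh$values, expected, tolerance = 1e-12)
})

test_that("FC templates equal the brute-force average of per-run correlations", {
  ds <- tiny_dataset(seed = 4)
  tmpl <- build_templates(ds, mode = "fc")
  subs <- isfcdecode:::run_subjects(ds)
  labs <- task_labels(ds)
  per_subject <- lapply(unique(subs), function(s) {
    sel <- which(subs == s & labs == "tax")
    mats <- lapply(ds$runs[sel], function(r) cor(t(r$data)))
    Reduce(`+`, mats) / length(mats)
  })
  oracle <- Reduce(`+`, per_subject) / length(per_subject)
  expect_equal(tmpl$templates$tax$values, oracle, tolerance = 1e-12)
})

test_that("classification picks the template with the larger correlation", {
  # hand-built FC-mode case: the run's correlation matrix is exactly the tax
  # template, so the tax score is 1
  set.seed(6)
  P <- 3; N <- 30
  run <- random_run(P = P, N = N, subject_id = "test", task = "tax")
  C_r <- cor(t(run$data))
  other <- matrix(c(1, -0.5, 0.2, -0.5, 1, -0.1, 0.2, -0.1, 1), 3, 3)
  tmpl <- structure(list(
    templates = list(beh = isfcdecode:::new_conn_matrix(other, "fc", FALSE, TRUE),
                     tax = isfcdecode:::new_conn_matrix(C_r, "fc", FALSE, TRUE)),
    references = list(), training_subjects = c("x", "y"),
    mode = "fc", tasks = c("beh", "tax")), class = "template_set")
  got <- classify_run(run, tmpl)
  expect_equal(as.character(got), "tax")
  idx <- edge_index(P, TRUE)
  s_beh <- cor(C_r[idx$lin], other[idx$lin])
  expect_equal(unname(attr(got, "scores")), c(s_beh, 1), tolerance = 1e-12)
  # exactly tied scores fall back to the first task, with a warning
  tmpl$templates$beh <- tmpl$templates$tax
  expect_warning(tie <- classify_run(run, tmpl), "tied")
  expect_equal(as.character(tie), "beh")
})

test_that("LOSOCV yields one prediction per run and perfect recovery without intrinsic noise", {
  ds <- tiny_dataset(seed = 7)
  fit <- losocv(ds, mode = "isfc")
  expect_s3_class(fit, "isfc_losocv")
  expect_equal(nrow(fit$predictions), length(ds$runs))
  expect_equal(fit$accuracy, mean(fit$predictions$predicted == fit$predictions$true))
  expect_length(fit$per_subject, 4)
  two <- generate_dataset(generator_config(K = 2, runs_per_task = 2, P = 12,
                                           N = 60, n_networks = 3, L = 3,
                                           L_int = 3, seed = 1))
  expect_error(losocv(two), "at least 3")

  sep <- generate_dataset(generator_config(K = 4, runs_per_task = 2, P = 12,
                                           N = 60, n_networks = 3, L = 3,
                                           L_int = 3, sigma_shared = 1,
                                           sigma_intrinsic = 0, seed = 8))
  expect_equal(losocv(sep, mode = "isfc")$accuracy, 1.0)
})

test_that("similarity analysis enumerates complementary half-splits once", {
  ds4 <- tiny_dataset(seed = 9)           # K = 4
  tab <- similarity_analysis(ds4)
  expect_equal(nrow(tab), 3)              # choose(4,2)/2
  expect_true(all(is.finite(tab$within)) && all(is.finite(tab$between)))
  ds6 <- reduced_dataset(seed = 10)       # K = 6
  expect_equal(nrow(similarity_analysis(ds6)), 10)   # choose(6,3)/2
  odd <- ds6
  keep <- isfcdecode:::run_subjects(ds6) != "sub06"
  odd$runs <- ds6$runs[keep]; odd$subjects <- ds6$subjects[1:5]; odd$K <- 5
  expect_error(similarity_analysis(odd), "even")
})

test_that("subnetwork-restricted accuracy is consistent with unrestricted LOSOCV", {
  ds <- reduced_dataset(seed = 11)
  idx <- edge_index(24, TRUE)
  full <- losocv(ds, mode = "isfc")
  all_edges <- losocv(ds, mode = "isfc", subset = seq_len(idx$n_edges))
  expect_equal(all_edges$accuracy, full$accuracy)

  sub <- subnetwork_classification(ds)
  expect_s3_class(sub, "subnet_accuracy")
  n <- length(sub$networks)
  expect_equal(dim(sub$accuracy), c(n, n))
  expect_equal(sub$accuracy, t(sub$accuracy))
  for (a in seq_len(n)) {
    expect_equal(sub$across_mean[[a]], mean(sub$accuracy[a, -a], na.rm = TRUE))
  }
  # one diagonal cell equals LOSOCV restricted to that within-network subset
  net1 <- sub$networks[1]
  cell <- losocv(ds, mode = "isfc",
                 subset = edge_subset(ds$atlas, idx, net1))$accuracy
  expect_equal(sub$accuracy[1, 1], cell)
})

test_that("scan-length windows are shared, seeded and bounded", {
  ds <- tiny_dataset(seed = 12)
  N <- ncol(ds$runs[[1]]$data)
  full <- losocv(ds, mode = "isfc")$accuracy
  sl <- scanlength_analysis(ds, lengths = N, reps = 3, seed = 1)
  expect_equal(unname(sl$mean_accuracy), full)     # only one possible window
  expect_true(all(sl$starts == 1))
  expect_error(scanlength_analysis(ds, lengths = N + 1), "exceeds")
  a <- scanlength_analysis(ds, lengths = c(20, 40), reps = 2, seed = 31)
  b <- scanlength_analysis(ds, lengths = c(20, 40), reps = 2, seed = 31)
  expect_identical(a$starts, b$starts)
  expect_identical(a$accuracy, b$accuracy)
})
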