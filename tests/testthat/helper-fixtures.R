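# Shared fixtures.  Expensive objects (the reference cohort and trained
# networks) are built once per test run and memoized here.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

# scaled-down reference analysis conditions used across tests: a
# 50-subject cohort (one trial per subject and class), temporally
# decimated inputs and a small four-stream CNN
ref_decimate <- c(markers = 8L, grf = 8L, emg = 64L, fm = 64L)

ref_quads_hyper <- function() {
  list(filters = c(8L, 16L), kernel = 5L, stride = 2L, dropout = 0,
       embed = 16L, head = 32L, shapes = decimated_shapes(ref_decimate))
}

ref_cohort <- function() memo("ref_cohort", generate_cohort(50, 1, seed = 1))

small_cohort <- function() memo("small_cohort", generate_cohort(6, 2, seed = 3))

# plan + one trained fold of the reference quads CNN
ref_fold_fit <- function() {
  memo("ref_fold_fit", {
    cohort <- ref_cohort()
    plan <- split_samples_kfold(cohort$labels, k = 10, seed = 1)
    fold <- plan$folds[[1]]
    std <- standardize_trials(cohort$trials,
                              stats_trials = cohort$trials[fold$train])
    spec <- model_spec("quads_cnn", c("markers", "grf", "emg", "fm"),
                       ref_quads_hyper())
    net <- build_model(spec, seed = 11)
    y <- cohort$labels$class
    train_network(net,
                  stack_inputs(std$trials[fold$train], decimate = ref_decimate),
                  y[fold$train],
                  stack_inputs(std$trials[fold$val], decimate = ref_decimate),
                  y[fold$val],
                  train_config(max_epochs = 60, patience = 20, seed = 5))
    list(cohort = cohort, plan = plan, fold = fold, std = std, net = net)
  })
}

# full experiment-1 cross-validation of the reference quads CNN and the
# LDA baseline
ref_cv <- function() {
  memo("ref_cv", {
    cohort <- ref_cohort()
    plan <- split_samples_kfold(cohort$labels, k = 10, seed = 1)
    quads <- cross_validate(
      model_spec("quads_cnn", c("markers", "grf", "emg", "fm"),
                 ref_quads_hyper()),
      cohort, plan,
      train_cfg = train_config(max_epochs = 60, patience = 20),
      decimate = ref_decimate, seed = 2)
    lda <- cross_validate(
      model_spec("lda", "markers",
                 list(flatten_decimate = 16L, n_pc = 50L)),
      cohort, plan, seed = 2)
    list(quads = quads, lda = lda)
  })
}

# tiny bias-free ReLU CNN over shrunken modality shapes, for relevance
# conservation work
tiny_shapes <- list(markers = c(40L, 6L), grf = c(40L, 4L),
                    emg = c(60L, 3L), fm = c(60L, 5L))

tiny_quads <- function(bias = FALSE, seed = 3) {
  build_model(model_spec(
    "quads_cnn", c("markers", "grf", "emg", "fm"),
    list(filters = c(4L, 6L), kernel = 3L, stride = 2L, dropout = 0,
         embed = 8L, head = 8L, bias = bias, shapes = tiny_shapes)),
    seed = seed)
}

random_tiny_inputs <- function() {
  lapply(tiny_shapes, function(s) matrix(rnorm(prod(s)), s[1], s[2]))
}

# a hand-weighted single-dense-layer network over a 1-channel sequence:
# logits = W' x (+ b); used as an analytically tractable fixture
linear_net <- function(w, n_classes = 1L, b = NULL) {
  T <- nrow(w)
  dense <- gaitxai:::ly_dense(T, n_classes, bias = !is.null(b))
  dense$params$W$W <- w
  if (!is.null(b)) dense$params$b$W <- b
  gaitxai:::new_network(
    streams = list(list(modality = "markers",
                        layers = list(gaitxai:::ly_flatten()),
                        in_shape = c(T, 1L))),
    head = list(dense), merge = "vector_concat",
    family = "custom", n_classes = n_classes)
}

expect_no_subject_overlap <- function(plan, labels) {
  for (fold in plan$folds) {
    tr <- unique(labels$subject_id[fold$train])
    va <- unique(labels$subject_id[fold$val])
    te <- unique(labels$subject_id[fold$test])
    expect_length(intersect(tr, te), 0)
    expect_length(intersect(va, te), 0)
    expect_length(intersect(tr, va), 0)
  }
}
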