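# Shared fixtures, all generated in code at test time.

# single rasterised ellipse mask (full axes L, D) on a square canvas
ellipse_mask <- function(L, D, canvas = c(112L, 112L), orientation = 0,
                         centre = (canvas - 1) / 2) {
  shape <- lv_shape_spec(L, D, per_cycle_ef = 50, canvas = canvas,
                         centre = centre, orientation = orientation)
  render_masks(list(long = L, short = D), shape)$masks[, , 1]
}

# (features, length) rows derived from rasterised ellipses; target is the
# generating long axis plus optional Gaussian noise
synth_feature_data <- function(n, seed = 1L, noise_sd = 0) {
  set.seed(seed)
  L <- runif(n, 50, 95)
  D <- runif(n, 0.35, 0.6) * L
  th <- runif(n, 0, pi)
  rows <- lapply(seq_len(n), function(i) {
    f <- extract_features(ellipse_mask(L[i], D[i], orientation = th[i]))
    features_row(f)
  })
  dat <- as.data.frame(do.call(rbind, rows))
  dat$length <- L + rnorm(n, 0, noise_sd)
  dat
}

# brute-force pairwise AUC: P(score_pos > score_neg), ties counting 1/2
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# literal step-by-step refinement oracle, independent of refine_jeffrey():
# (1) raw extreme, (2) top fraction of the whole curve, (3) top fraction of
# the ED..ES window, (4) mean of everything selected
jeffrey_literal <- function(areas, i_ed, i_es, fraction = 0.10) {
  sel_ed <- c(areas[i_ed],
              sort(areas, decreasing = TRUE)[1:max(1, ceiling(fraction * length(areas)))],
              sort(areas[i_ed:i_es], decreasing = TRUE)[
                1:max(1, ceiling(fraction * length(i_ed:i_es)))])
  sel_es <- c(areas[i_es],
              sort(areas)[1:max(1, ceiling(fraction * length(areas)))],
              sort(areas[i_ed:i_es])[1:max(1, ceiling(fraction * length(i_ed:i_es)))])
  c(a_ed = mean(sel_ed), a_es = mean(sel_es))
}

# hand-built CycleSet (bypasses detection) for refinement-only tests
manual_cycles <- function(curve, ed_frames, es_frames) {
  structure(list(pairs = data.frame(ed_frame = ed_frames, es_frame = es_frames),
                 curve_ref = curve), class = "CycleSet")
}

# stub base learner that always predicts one value
stub_model <- function(value) structure(list(value = value), class = "mean_model")

# LengthModel whose four base learners are constant stubs
stub_length_model <- function(v1, v2, v3, v4) {
  structure(list(
    fits = list(extra_trees = stub_model(v1), adaboost = stub_model(v2),
                lasso = stub_model(v3),
                stack = structure(list(members = list(ridge = stub_model(v4)),
                                       meta = stub_model(v4),
                                       member_names = "ridge"),
                                  class = "stack_model")),
    spec = ensemble_spec(), feature_names = c("area", "height"),
    cv_scores = NULL), class = "LengthModel")
}
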