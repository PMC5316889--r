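# Shared fixture builders. Everything is generated in code at test time;
# expensive objects are memoized per session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

small_grid <- function() memo("small_grid", make_grid(c(8, 8, 8), "full"))

ref_grid <- function() {
  memo("ref_grid", make_grid(c(12, 12, 12), "ellipsoid", semi_axes = c(5, 5, 5)))
}

ref_truth <- function() memo("ref_truth", make_ground_truth(ref_grid(), seed = 2))

ref_reference <- function() {
  memo("ref_reference", generate_reference_signature(ref_grid(), 0.3, seed = 3))
}

# The reference simulation: 20 subjects x generic design (~50 painful
# trials) on the 12^3 ellipsoid grid, default planted truth.
ref_datasets <- function(n = 20) {
  memo(paste0("ref_datasets_", n), {
    des <- make_study_design("generic")
    lapply(seq_len(n), function(i) {
      generate_trial_dataset(des, ref_grid(), ref_truth(),
                             sprintf("s%02d", i), seed = 100 + i)
    })
  })
}

ref_signature <- function() {
  memo("ref_signature",
       develop_signature(ref_datasets(), ref_reference(), seed = 1))
}

ref_loso <- function() {
  memo("ref_loso",
       loso_develop_and_apply(ref_datasets(), ref_reference(), seed = 1))
}

# Hand-built dataset wrapping explicit matrices (for arithmetic fixtures).
manual_dataset <- function(X, ratings, intensity, grid,
                           conditions = NULL, painful = NULL) {
  n <- nrow(X)
  structure(list(
    subject_id = "manual", X = X, ratings = ratings, intensity = intensity,
    conditions = conditions %||% data.frame(cue = rep(1, n)),
    perceived_control_rating = NULL,
    painful_flag = painful %||% rep(TRUE, n),
    excluded_flag = rep(FALSE, n), excluded_reason = rep("", n),
    mediation_flag = rep(TRUE, n),
    run = rep(1L, n), trial = seq_len(n),
    truth_amplitude = rep(0, n), rating_bounds = c(0, 10),
    design_label = "manual", grid = grid
  ), class = "trial_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
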