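#' Read and write volumes as NIfTI
#'
#' `write_volume()` serializes a weight map (3-D), a mask, or a trials x
#' voxels matrix (as a 4-D stack, one volume per trial) to NIfTI;
#' `read_volume()` reads it back. When an expected `grid` is supplied the
#' on-disk shape and voxel size must match exactly — mismatches are errors,
#' never silent resampling — and in-mask values are returned in the grid's
#' linearization (a vector for 3-D images, a trials x voxels matrix for
#' 4-D stacks).
#'
#' @param x a `weight_map`, a numeric vector (with `grid`), a 3-D array, or
#'   a trials x voxels matrix (with `grid`).
#' @param path file path (`.nii` or `.nii.gz`).
#' @param grid optional `grid_spec`.
#' @param voxel_size voxel dimensions recorded in the header.
#' @return `write_volume()` returns `path` invisibly; `read_volume()`
#'   returns an array, or a vector/matrix when `grid` is given.
#' @export
write_volume <- function(x, path, grid = NULL, voxel_size = c(1, 1, 1)) {
  arr <- if (inherits(x, "weight_map")) {
    vec_to_vol(x$values, x$grid)
  } else if (is.matrix(x)) {
    if (is.null(grid)) stop("writing a trial stack requires `grid`")
    a <- array(0, dim = c(grid$shape, nrow(x)))
    for (t in seq_len(nrow(x))) a[, , , t] <- vec_to_vol(x[t, ], grid)
    a
  } else if (!is.null(dim(x))) {
    x
  } else {
    if (is.null(grid)) stop("writing a voxel vector requires `grid`")
    vec_to_vol(x, grid)
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, grid = NULL, voxel_size = c(1, 1, 1)) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (!is.null(grid)) {
    if (!identical(dim(arr)[1:3], as.integer(grid$shape))) {
      stop("grid mismatch: on-disk volume shape differs from the expected grid")
    }
    pd <- RNifti::pixdim(img)[1:3]
    if (any(abs(pd - voxel_size) > 1e-6)) {
      stop("affine mismatch: on-disk voxel size differs from the expected one")
    }
    if (length(dim(arr)) == 3) {
      return(vol_to_vec(arr, grid))
    }
    n_t <- dim(arr)[4]
    out <- matrix(NA_real_, n_t, grid$n_vox)
    for (t in seq_len(n_t)) out[t, ] <- vol_to_vec(arr[, , , t], grid)
    return(out)
  }
  arr
}

meta_columns <- c("subject", "run", "trial", "intensity_level", "rating",
                  "painful_flag", "excluded_flag")

#' Read and write trial metadata tables
#'
#' Tab-separated, header row, UTF-8. Mandated columns: `subject`, `run`,
#' `trial`, `intensity_level`, `rating`, `painful_flag`, `excluded_flag`
#' (flags coded 0/1); condition-code and any other columns are preserved.
#'
#' @param meta a data frame (or a `trial_dataset`, converted via
#'   [meta_from_dataset()]).
#' @param path file path.
#' @return `read_meta()` returns the validated data frame.
#' @export
write_meta <- function(meta, path) {
  if (inherits(meta, "trial_dataset")) meta <- meta_from_dataset(meta)
  missing <- setdiff(meta_columns, names(meta))
  if (length(missing)) {
    stop(sprintf("missing mandated metadata column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  utils::write.table(meta, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_meta
#' @export
read_meta <- function(path) {
  meta <- utils::read.delim(path, check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(meta_columns, names(meta))
  if (length(missing)) {
    stop(sprintf("missing mandated metadata column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  for (fl in c("painful_flag", "excluded_flag")) {
    if (!all(meta[[fl]] %in% c(0, 1))) {
      stop(sprintf("column %s must contain only 0/1", fl))
    }
  }
  meta
}

#' @rdname write_meta
#' @param dataset a `trial_dataset`.
#' @export
meta_from_dataset <- function(dataset) {
  df <- data.frame(subject = dataset$subject_id, run = dataset$run,
                   trial = dataset$trial,
                   intensity_level = dataset$intensity,
                   rating = dataset$ratings,
                   painful_flag = as.integer(dataset$painful_flag),
                   excluded_flag = as.integer(dataset$excluded_flag))
  for (f in names(dataset$conditions)) df[[f]] <- dataset$conditions[[f]]
  if (!is.null(dataset$perceived_control_rating)) {
    df$perceived_control_rating <- dataset$perceived_control_rating
  }
  df$mediation_flag <- as.integer(dataset$mediation_flag)
  df
}

#' Default pipeline configuration
#'
#' The reference simulation and analysis settings used by [run_pipeline()]:
#' a 12x12x12 grid with an ellipsoidal mask, the generic study design, 20
#' subjects, the default planted ground truth, all-component PCR with
#' 10-fold cross-validation, FDR q = 0.05, 15-voxel minimum region size,
#' 26-neighbourhood, VIF threshold 2.5, and 1000 bootstrap/permutation
#' iterations (raise for production inference).
#'
#' @param seed master seed; stage seeds derive from it.
#' @return a nested list; serialize with [write_config()].
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    grid = list(shape = c(12, 12, 12), mask_rule = "ellipsoid",
                semi_axes = c(5, 5, 5)),
    design = list(preset = "generic"),
    truth = list(),
    n_subjects = 20,
    reference = list(support_fraction = 0.3),
    decoder = list(n_components = "all", k = 10, folds = "random"),
    fdr_q = 0.05, min_size = 15, connectivity = 26,
    vif_threshold = 2.5,
    n_boot = 1000, n_perm = 1000,
    write_volumes = TRUE
  )
}

#' @rdname default_config
#' @param config a configuration list.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) yaml::read_yaml(path)

log_line <- function(out_dir, fmt, ...) {
  cat(sprintf(paste0(fmt, "\n"), ...),
      file = file.path(out_dir, "pipeline_log.txt"), append = TRUE)
}

config_objects <- function(config) {
  g <- do.call(make_grid, config$grid)
  tr_args <- c(list(grid = g, seed = config$seed), config$truth)
  truth <- do.call(make_ground_truth, tr_args)
  design <- do.call(make_study_design, config$design)
  ref <- generate_reference_signature(g, config$reference$support_fraction,
                                      seed = config$seed + 1000)
  list(grid = g, truth = truth, design = design, reference = ref)
}

#' Run a pipeline stage
#'
#' Orchestrates the stages over an output directory of standard-format
#' artifacts, logging seeds, trial counts before/after each filter and
#' every threshold used to `pipeline_log.txt`.
#'
#' * `simulate` — per-subject metadata TSV + (optionally) 4-D trial stacks,
#'   the analysis mask, the reference signature, and the ground-truth
#'   sidecar JSON.
#' * `betaseries` — beta-series estimation of a BOLD run given in
#'   `config$bold` (paths to a 4-D NIfTI and an events TSV); writes a beta
#'   stack and a QC table.
#' * `develop` — full signature development from the simulated artifacts;
#'   writes the signature, t/p maps, FDR mask, region table, subject table.
#' * `apply` — scores every subject's trials with the developed signature;
#'   writes `responses.tsv`.
#' * `infer` — multilevel GLM (rating on z-scored signature response and
#'   intensity) and mediation of the first condition factor through the
#'   z-scored response with intensity as covariate; writes TSV tables.
#' * `report` — one-page text summary of what is on disk.
#'
#' @param command one of `"simulate"`, `"betaseries"`, `"develop"`,
#'   `"apply"`, `"infer"`, `"report"`.
#' @param config a [default_config()]-style list (or a YAML path).
#' @param out_dir artifact directory (created if needed).
#' @return invisibly, a list of the stage's main in-memory results.
#' @export
run_pipeline <- function(command = c("simulate", "betaseries", "develop",
                                     "apply", "infer", "report"),
                         config = default_config(), out_dir) {
  command <- match.arg(command)
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- switch(command,
    simulate = stage_simulate(config, out_dir),
    betaseries = stage_betaseries(config, out_dir),
    develop = stage_develop(config, out_dir),
    apply = stage_apply(config, out_dir),
    infer = stage_infer(config, out_dir),
    report = stage_report(config, out_dir)
  )
  invisible(res)
}

stage_simulate <- function(config, out_dir) {
  obj <- config_objects(config)
  log_line(out_dir, "[simulate] seed=%d subjects=%d design=%s grid=%s n_vox=%d",
           config$seed, config$n_subjects, obj$design$label,
           paste(obj$grid$shape, collapse = "x"), obj$grid$n_vox)
  write_volume(obj$grid$mask + 0, file.path(out_dir, "mask.nii"))
  write_volume(obj$reference, file.path(out_dir, "reference_signature.nii"))
  truth_sidecar <- list(
    subregions = lapply(obj$truth$subregions, function(s) {
      list(name = s$name, sign = s$sign, n_voxels = length(s$voxels),
           voxels = s$voxels)
    }),
    achieved_overlap = obj$truth$achieved_overlap,
    effect_sizes = obj$truth[c("intensity_gain", "endogenous_gain",
                               "manipulation_path", "mediator_path",
                               "direct_path", "subject_sd", "trial_sd",
                               "voxel_noise_sd", "rating_noise_sd")],
    seed = obj$truth$seed
  )
  jsonlite::write_json(truth_sidecar, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  datasets <- lapply(seq_len(config$n_subjects), function(i) {
    d <- generate_trial_dataset(obj$design, obj$grid, obj$truth,
                                subject_id = sprintf("s%02d", i),
                                seed = config$seed + i)
    write_meta(d, file.path(out_dir, sprintf("%s_meta.tsv", d$subject_id)))
    if (isTRUE(config$write_volumes)) {
      write_volume(d$X, file.path(out_dir, sprintf("%s_trials.nii", d$subject_id)),
                   grid = obj$grid)
    }
    log_line(out_dir, "[simulate] %s: trials=%d painful=%d nonpainful=%d seed=%d",
             d$subject_id, nrow(d$X), sum(d$painful_flag),
             sum(!d$painful_flag), config$seed + i)
    d
  })
  list(datasets = datasets, grid = obj$grid, truth = obj$truth,
       design = obj$design, reference = obj$reference)
}

stage_betaseries <- function(config, out_dir) {
  if (is.null(config$bold)) stop("betaseries: config$bold must give `volume` and `events` paths")
  grid <- read_grid(out_dir)
  bold <- read_volume(config$bold$volume, grid)  # scans x voxels
  events <- utils::read.delim(config$bold$events)
  des <- build_single_trial_design(events, n_scans = nrow(bold),
                                   tr = config$bold$tr %||% 2)
  fit <- estimate_trial_betas(bold, des, vif_threshold = config$vif_threshold)
  write_volume(fit$betas, file.path(out_dir, "betas.nii"), grid = grid)
  utils::write.table(
    data.frame(trial = des$trial_id, vif = des$vif,
               excluded = as.integer(des$trial_id %in% fit$qc$excluded_trials)),
    file.path(out_dir, "betaseries_qc.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  log_line(out_dir, "[betaseries] trials=%d excluded(vif>%.2f)=%d",
           length(des$trial_id), config$vif_threshold,
           length(fit$qc$excluded_trials))
  fit
}

read_grid <- function(out_dir) {
  mask <- read_volume(file.path(out_dir, "mask.nii"))
  make_grid(dim(mask), "custom", mask = mask > 0)
}

load_datasets <- function(config, out_dir) {
  grid <- read_grid(out_dir)
  metas <- sort(list.files(out_dir, "_meta\\.tsv$", full.names = TRUE))
  if (length(metas) == 0) stop("develop: no simulated metadata found; run simulate first")
  datasets <- lapply(metas, function(mp) {
    meta <- read_meta(mp)
    sid <- meta$subject[1]
    X <- read_volume(file.path(out_dir, sprintf("%s_trials.nii", sid)), grid)
    factors <- setdiff(names(meta),
                       c(meta_columns, "perceived_control_rating", "mediation_flag"))
    structure(list(
      subject_id = sid, X = X, ratings = meta$rating,
      intensity = meta$intensity_level,
      conditions = meta[, factors, drop = FALSE],
      perceived_control_rating = meta$perceived_control_rating,
      painful_flag = meta$painful_flag == 1,
      excluded_flag = meta$excluded_flag == 1,
      excluded_reason = rep("", nrow(meta)),
      mediation_flag = (meta$mediation_flag %||% meta$painful_flag) == 1,
      run = meta$run, trial = meta$trial,
      rating_bounds = range(meta$rating), grid = grid
    ), class = "trial_dataset")
  })
  list(grid = grid, datasets = datasets)
}

stage_develop <- function(config, out_dir) {
  ld <- load_datasets(config, out_dir)
  if (length(ld$datasets) < 3) stop("develop: signature development needs at least 3 subjects")
  ref <- weight_map(read_volume(file.path(out_dir, "reference_signature.nii"),
                                ld$grid), ld$grid, "reference")
  sig <- develop_signature(ld$datasets, ref,
                           n_components = config$decoder$n_components,
                           k = config$decoder$k, folds = config$decoder$folds,
                           q = config$fdr_q, min_size = config$min_size,
                           connectivity = config$connectivity,
                           seed = config$seed)
  write_volume(sig$weights, file.path(out_dir, "signature.nii"))
  write_volume(sig$t, file.path(out_dir, "signature_t.nii"), grid = ld$grid)
  write_volume(sig$p, file.path(out_dir, "signature_p.nii"), grid = ld$grid)
  write_volume(sig$q_mask + 0, file.path(out_dir, "signature_qmask.nii"),
               grid = ld$grid)
  utils::write.table(
    do.call(rbind, lapply(sig$regions, function(r) {
      data.frame(label = r$label, size = r$size, mean_weight = r$mean_weight,
                 sign = r$sign)
    })) %||% data.frame(label = character(), size = integer(),
                        mean_weight = numeric(), sign = integer()),
    file.path(out_dir, "regions.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  utils::write.table(
    data.frame(subject = vapply(sig$models, `[[`, character(1), "subject_id"),
               cv_r = vapply(sig$models, `[[`, numeric(1), "cv_r"),
               n_trials_used = vapply(sig$models, `[[`, numeric(1),
                                      "n_trials_used")),
    file.path(out_dir, "subject_models.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  log_line(out_dir,
           "[develop] subjects=%d q=%.3f surviving=%d regions=%d min_size=%d seed=%d",
           length(ld$datasets), config$fdr_q, sum(sig$q_mask),
           length(sig$regions), config$min_size, config$seed)
  sig
}

stage_apply <- function(config, out_dir) {
  ld <- load_datasets(config, out_dir)
  sig <- weight_map(read_volume(file.path(out_dir, "signature.nii"), ld$grid),
                    ld$grid, "group signature")
  rows <- do.call(rbind, lapply(ld$datasets, function(d) {
    data.frame(subject = d$subject_id, run = d$run, trial = d$trial,
               response = signature_response(d$X, sig),
               rating = d$ratings, intensity_level = d$intensity,
               painful_flag = as.integer(d$painful_flag),
               excluded_flag = as.integer(d$excluded_flag))
  }))
  utils::write.table(rows, file.path(out_dir, "responses.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  log_line(out_dir, "[apply] subjects=%d trials=%d", length(ld$datasets),
           nrow(rows))
  rows
}

stage_infer <- function(config, out_dir) {
  ld <- load_datasets(config, out_dir)
  resp <- utils::read.delim(file.path(out_dir, "responses.tsv"))
  sids <- vapply(ld$datasets, `[[`, character(1), "subject_id")
  Y <- X <- xs <- ms <- cv <- vector("list", length(sids))
  for (i in seq_along(sids)) {
    d <- ld$datasets[[i]]
    inc <- which(d$painful_flag & !d$excluded_flag & d$mediation_flag)
    r <- resp[resp$subject == sids[i], ]
    Y[[i]] <- d$ratings[inc]
    X[[i]] <- cbind(signature = zscore_within(r$response[inc]),
                    intensity = d$intensity[inc])
    xs[[i]] <- d$conditions[inc, 1]
    ms[[i]] <- cbind(signature = zscore_within(r$response[inc]))
    cv[[i]] <- cbind(intensity = d$intensity[inc])
  }
  glm_res <- multilevel_glm(Y, X, n_boot = config$n_boot, seed = config$seed)
  med <- mediate_multilevel(xs, ms, Y, covariates = cv,
                            n_boot = config$n_boot, seed = config$seed)
  utils::write.table(cbind(glm_res$group,
                           unique_R2 = glm_res$unique_R2,
                           R2_full = glm_res$R2_full),
                     file.path(out_dir, "glm.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(med$paths, file.path(out_dir, "mediation.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  log_line(out_dir, "[infer] subjects=%d n_boot=%d seed=%d R2_full=%.4f",
           length(sids), config$n_boot, config$seed, glm_res$R2_full)
  list(glm = glm_res, mediation = med)
}

stage_report <- function(config, out_dir) {
  files <- list.files(out_dir)
  lines <- c("pipeline artifact report", paste0("  ", files))
  writeLines(lines, file.path(out_dir, "report.txt"))
  log_line(out_dir, "[report] %d artifacts", length(files))
  lines
}
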