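#' Canonical tooth labels and label schemes
#'
#' The 16-type label set covers the 8 maxillary anatomical tooth types,
#' sided left/right. Coarser schemes collapse it to 8 broader categories
#' (side dropped) or 4 major categories (incisors, canines, premolars,
#' molars). Integer codes used by the classifier are assigned
#' alphabetically within each scheme.
#'
#' @return `tooth_labels_16()`: the 16 canonical label strings.
#' @export
tooth_labels_16 <- function() {
  types <- c("Central Incisor", "Lateral Incisor", "Canine",
             "1st Premolar", "2nd Premolar",
             "1st Molar", "2nd Molar", "3rd Molar")
  as.vector(t(outer(types, c("(L)", "(R)"), paste)))
}

anatomical_type <- function(label16) {
  sub(" \\((L|R)\\)$", "", label16)
}

#' @rdname tooth_labels_16
#' @param granularity 16, 8 or 4.
#' @return `label_scheme()`: an object of class `label_scheme` with the
#'   class names of the scheme and the collapse map from the 16-type set.
#' @export
label_scheme <- function(granularity = c(16L, 8L, 4L)) {
  granularity <- as.integer(granularity[1L])
  if (!granularity %in% c(16L, 8L, 4L))
    stop("granularity must be 16, 8 or 4")
  l16 <- tooth_labels_16()
  map <- switch(as.character(granularity),
    "16" = stats::setNames(l16, l16),
    "8" = stats::setNames(tolower(anatomical_type(l16)), l16),
    "4" = {
      type <- anatomical_type(l16)
      coarse <- ifelse(grepl("Incisor", type), "incisors",
                ifelse(type == "Canine", "canines",
                ifelse(grepl("Premolar", type), "premolars", "molars")))
      stats::setNames(coarse, l16)
    })
  structure(list(granularity = granularity,
                 classes = sort(unique(unname(map))),
                 map = map),
            class = "label_scheme")
}

#' Collapse 16-type labels to a coarser scheme
#'
#' @param label16 character vector of canonical 16-type labels.
#' @param scheme a [label_scheme()].
#' @return character vector of scheme-level class names.
#' @examples
#' collapse_labels("1st Molar (L)", label_scheme(4))   # "molars"
#' @export
collapse_labels <- function(label16, scheme) {
  stopifnot(inherits(scheme, "label_scheme"))
  label16 <- as.character(label16)
  bad <- setdiff(label16, names(scheme$map))
  if (length(bad) > 0L)
    stop("unknown label(s): ", paste(unique(bad), collapse = ", "),
         "; canonical names are: ", paste(tooth_labels_16(), collapse = ", "))
  unname(scheme$map[label16])
}

#' Integer codes for scheme classes
#'
#' Codes are `0..(K-1)` in alphabetical class order, the convention the
#' classifier's sparse categorical cross-entropy expects.
#'
#' @param labels character vector of scheme-level class names.
#' @param scheme a [label_scheme()].
#' @return integer vector of codes.
#' @export
label_codes <- function(labels, scheme) {
  match(as.character(labels), scheme$classes) - 1L
}

#' Train/test split configuration
#'
#' @param train_fraction fraction allocated to training (default 0.70,
#'   floor rounding; `floor(0.70 * 2688) = 1881` reproduces the study-scale
#'   1881/807 split).
#' @param stratified sample within classes so class proportions carry over
#'   (default `TRUE`); per-class counts are floored, then topped up from
#'   the largest classes to hit the exact global training count.
#' @param group_aware if `TRUE`, split by source group (e.g. the physical
#'   tooth an augmented variant came from) instead of by object, so
#'   variants of one tooth never straddle the split. Default `FALSE`: the
#'   default protocol splits the augmented objects directly, which lets
#'   variants of one tooth appear on both sides (information leakage); the
#'   flag exists to quantify that effect.
#' @param seed integer seed.
#' @return an object of class `dataset_split_config`.
#' @export
dataset_split_config <- function(train_fraction = 0.70, stratified = TRUE,
                                 group_aware = FALSE, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  structure(list(train_fraction = as.numeric(train_fraction),
                 stratified = isTRUE(stratified),
                 group_aware = isTRUE(group_aware),
                 seed = as.integer(seed)),
            class = "dataset_split_config")
}

#' Split a dataset into train and test subsets
#'
#' The training side gets exactly `floor(train_fraction * N)` objects
#' (non-group-aware modes); train and test are disjoint and exhaustive.
#'
#' @param objects a data.frame with columns `id` (unique object
#'   identifiers), `label` (class used for stratification), and, if
#'   `group_aware`, `group`.
#' @param cfg a [dataset_split_config()].
#' @return a list with `train_ids` and `test_ids` (values of
#'   `objects$id`).
#' @export
split_dataset <- function(objects, cfg = dataset_split_config()) {
  stopifnot(inherits(cfg, "dataset_split_config"))
  if (nrow(objects) < 2L) stop("need at least 2 objects to split")
  if (anyDuplicated(objects$id)) stop("object ids must be unique")
  N <- nrow(objects)
  n_train <- floor(cfg$train_fraction * N)
  with_seed(cfg$seed, {
    if (cfg$group_aware) {
      if (is.null(objects$group)) stop("group_aware split needs a group column")
      groups <- unique(as.character(objects$group))
      ord <- sample(groups)
      sizes <- table(as.character(objects$group))[ord]
      csum <- cumsum(sizes)
      k <- which.min(abs(csum - n_train))
      train_groups <- ord[seq_len(k)]
      tr <- objects$id[as.character(objects$group) %in% train_groups]
    } else if (cfg$stratified) {
      lab <- as.character(objects$label)
      counts <- table(lab)
      if (any(counts < 2L))
        stop("stratified split infeasible: class \"",
             names(counts)[counts < 2L][1L],
             "\" has fewer than 2 objects")
      take <- floor(cfg$train_fraction * counts)
      take <- pmin(pmax(take, 1L), counts - 1L)
      deficit <- n_train - sum(take)
      # adjust from the largest classes (ties: alphabetical), round-robin
      ord_cls <- names(sort(counts, decreasing = TRUE))
      i <- 1L
      guard <- 0L
      while (deficit != 0L) {
        cl <- ord_cls[(i - 1L) %% length(ord_cls) + 1L]
        if (deficit > 0L && take[cl] < counts[cl] - 1L) {
          take[cl] <- take[cl] + 1L; deficit <- deficit - 1L
        } else if (deficit < 0L && take[cl] > 1L) {
          take[cl] <- take[cl] - 1L; deficit <- deficit + 1L
        }
        i <- i + 1L
        if ((guard <- guard + 1L) > 10L * length(ord_cls) + abs(n_train))
          stop("stratified split infeasible: cannot reach the global ",
               "training count with every class on both sides")
      }
      tr <- unlist(lapply(names(counts), function(cl) {
        ids <- objects$id[lab == cl]
        ids[sample.int(length(ids), take[cl])]
      }), use.names = FALSE)
    } else {
      tr <- objects$id[sample.int(N, n_train)]
    }
    list(train_ids = tr, test_ids = setdiff(objects$id, tr))
  })
}

#' Experiment run configuration
#'
#' Bundles every stage's settings for [run_experiment()]. Defaults mirror
#' the study conditions: 28 subjects, a 900-triangle budget, 6-fold
#' augmentation (identity included) giving 448 -> 2688 objects, a 0.70
#' train fraction (1881/807), combined vertex + centroid features, and the
#' 2 x 128 GRU classifier at learning rate 0.0005.
#'
#' @param scheme_granularity 16, 8 or 4.
#' @param n_subjects synthetic subjects (ignored when `input_dir` given).
#' @param dense_faces pre-decimation face count for synthetic teeth.
#' @param triangle_budget decimation target (timesteps of the sequence).
#' @param subject_jitter synthetic shape jitter.
#' @param input_dir optional directory of mesh files with a `labels.csv`
#'   (columns file, label16, subject_id); replaces the synthetic generator.
#' @param variants_per_original augmentation expansion factor.
#' @param rotation_mode `"single"` or `"triple"`.
#' @param feature_subset `"both"`, `"vertices"` or `"centers"`.
#' @param face_order `"stored"` (decimator output order) or `"canonical"`
#'   (centroid z/y/x sort, a consistent spatial scan across meshes).
#' @param variant classifier variant.
#' @param recurrent_units,fc_units architecture sizes.
#' @param learning_rate Adam learning rate.
#' @param epochs,batch_size,early_stopping_patience training settings.
#' @param train_fraction,stratified,group_aware split settings.
#' @param seed master seed; stage seeds are derived from it.
#' @param out_dir output directory (reports, manifest, logs); `NULL`
#'   disables writing.
#' @return an object of class `run_config`.
#' @export
run_config <- function(scheme_granularity = 16L, n_subjects = 28L,
                       dense_faces = 20000L, triangle_budget = 900L,
                       subject_jitter = 0.05, input_dir = NULL,
                       variants_per_original = 6L,
                       rotation_mode = "single",
                       feature_subset = "both", face_order = "stored",
                       variant = "GRU",
                       recurrent_units = 128L, fc_units = 64L,
                       learning_rate = 5e-4, epochs = 100L,
                       batch_size = 32L, early_stopping_patience = 10L,
                       train_fraction = 0.70, stratified = TRUE,
                       group_aware = FALSE, seed = 1L, out_dir = NULL) {
  cfg <- as.list(environment())
  cfg$scheme_granularity <- as.integer(scheme_granularity)
  if (!cfg$scheme_granularity %in% c(4L, 8L, 16L))
    stop("scheme_granularity must be 4, 8 or 16")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown keys are rejected so typos fail loudly.
#'
#' @param path a `.yaml`/`.yml` or `.json` file whose keys are
#'   [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L)
    stop("unknown run_config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Run the end-to-end classification experiment
#'
#' Executes generate/load -> decimate -> augment -> collapse -> split ->
#' encode -> train -> evaluate. Every stage seed derives from the master
#' seed, so identical configurations give identical manifests and reports.
#' When `out_dir` is set, writes `report.json`, `report.csv`,
#' `confusion.csv`, `manifest.json`, `loss_curves.csv` and the resolved
#' configuration.
#'
#' @param cfg a [run_config()].
#' @param verbose print stage progress.
#' @return a list with `report` (an `evaluation_report`), `manifest`
#'   (stage input/output counts and seeds), `model`, and `history`.
#' @export
run_experiment <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  manifest <- list(seed = cfg$seed)

  # stage 1: obtain labeled meshes
  if (is.null(cfg$input_dir)) {
    say("generating synthetic dataset (%d subjects)", cfg$n_subjects)
    ds <- generate_dataset(synthetic_dataset_config(
      n_subjects = cfg$n_subjects, subject_jitter = cfg$subject_jitter,
      dense_faces = cfg$dense_faces, seed = cfg$seed))
    meshes <- ds$meshes
  } else {
    labels <- read_labels(file.path(cfg$input_dir, "labels.csv"))
    meshes <- lapply(seq_len(nrow(labels)), function(i)
      read_mesh(file.path(cfg$input_dir, labels$file[i]),
                label = labels$label16[i], source_id = labels$file[i]))
  }
  manifest$n_original <- length(meshes)

  # stage 2: decimate to the triangle budget
  say("decimating %d meshes to %d faces", length(meshes),
      cfg$triangle_budget)
  meshes <- lapply(meshes, decimate_mesh, target_faces = cfg$triangle_budget)
  manifest$triangle_budget <- cfg$triangle_budget

  # stage 3: augment
  policy <- augmentation_policy(
    variants_per_original = cfg$variants_per_original,
    seed = cfg$seed + 1L, rotation_mode = cfg$rotation_mode)
  meshes <- augment_dataset(meshes, policy)
  manifest$n_augmented <- length(meshes)
  say("augmented to %d objects", length(meshes))

  # stage 4: collapse labels
  scheme <- label_scheme(cfg$scheme_granularity)
  lab <- collapse_labels(vapply(meshes, function(m) m$label, character(1)),
                         scheme)
  codes <- label_codes(lab, scheme)

  # stage 5: split
  groups <- sub("#v\\d+$", "", vapply(meshes, function(m) m$source_id,
                                      character(1)))
  objects <- data.frame(id = seq_along(meshes), label = lab, group = groups)
  split <- split_dataset(objects, dataset_split_config(
    train_fraction = cfg$train_fraction, stratified = cfg$stratified,
    group_aware = cfg$group_aware, seed = cfg$seed + 2L))
  manifest$n_train <- length(split$train_ids)
  manifest$n_test <- length(split$test_ids)
  say("split: %d train / %d test", manifest$n_train, manifest$n_test)

  # stage 6: encode
  fdim <- c(both = 12L, vertices = 9L, centers = 3L)[[cfg$feature_subset]]
  X <- array(0, c(length(meshes), cfg$triangle_budget, fdim))
  for (i in seq_along(meshes))
    X[i, , ] <- to_feature_image(extract_features(
      meshes[[i]], subset = cfg$feature_subset,
      budget = cfg$triangle_budget, order = cfg$face_order))$pixels
  manifest$n_encoded <- dim(X)[1L]

  # stage 7: train
  mcfg <- model_config(variant = cfg$variant,
                       recurrent_units = cfg$recurrent_units,
                       fc_units = cfg$fc_units,
                       num_classes = cfg$scheme_granularity,
                       input_shape = c(cfg$triangle_budget, fdim),
                       learning_rate = cfg$learning_rate)
  model <- build_model(mcfg, seed = cfg$seed + 3L)
  model$class_names <- scheme$classes
  say("training %s (%d params)", cfg$variant, count_parameters(model))
  model <- train_model(model, X[split$train_ids, , , drop = FALSE],
                       codes[split$train_ids],
                       training_config(epochs = cfg$epochs,
                                       batch_size = cfg$batch_size,
                                       early_stopping_patience =
                                         cfg$early_stopping_patience,
                                       seed = cfg$seed + 4L))

  # stage 8: evaluate
  report <- evaluate_model(model, X[split$test_ids, , , drop = FALSE],
                           codes[split$test_ids])
  say("test accuracy: %.2f%%", report$accuracy)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, cfg$out_dir)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(model$history,
                     file.path(cfg$out_dir, "loss_curves.csv"),
                     row.names = FALSE)
    resolved <- unclass(cfg)
    resolved$input_dir <- if (is.null(cfg$input_dir)) "" else cfg$input_dir
    resolved$out_dir <- cfg$out_dir
    yaml::write_yaml(resolved, file.path(cfg$out_dir, "config.yaml"))
  }

  list(report = report, manifest = manifest, model = model,
       history = model$history)
}

#' Desk-scale synthetic classification benchmark
#'
#' A compact, fully reproducible end-to-end benchmark: 28 synthetic
#' subjects (448 teeth), 4-category scheme, a 160-triangle budget and no
#' augmentation, classified with the 2 x 128 GRU on combined
#' vertex + centroid features. Problem sizes are chosen so the whole run
#' takes a couple of minutes on one CPU while the classes remain cleanly
#' separable; see the methods vignette for the rationale.
#'
#' @param seed master seed.
#' @param n_subjects number of synthetic subjects (default 28).
#' @param triangle_budget sequence length (default 120).
#' @param variant classifier variant (default `"GRU"`).
#' @param feature_subset feature columns (default `"both"`).
#' @param epochs training epochs cap (default 80).
#' @return a list with `accuracy` (percent) and the full `report`.
#' @export
synthetic_benchmark <- function(seed = 1L, n_subjects = 28L,
                                triangle_budget = 120L, variant = "GRU",
                                feature_subset = "both", epochs = 80L) {
  cfg <- run_config(scheme_granularity = 4L, n_subjects = n_subjects,
                    dense_faces = 2000L, triangle_budget = triangle_budget,
                    variants_per_original = 1L, variant = variant,
                    feature_subset = feature_subset,
                    face_order = "canonical", epochs = epochs,
                    early_stopping_patience = 15L, seed = seed)
  res <- run_experiment(cfg)
  list(accuracy = res$report$accuracy, report = res$report,
       manifest = res$manifest)
}
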