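#' Session and cohort data model
#'
#' A *session* is one subject's interview: per-utterance feature matrices for
#' up to three modalities (A = audio, V = visual, T = text), all with the
#' same number of rows `n` (one row per utterance, chronological order), plus
#' a continuous severity label on a declared clinical scale.  A *cohort* is a
#' list of sessions sharing the same modality set and per-modality feature
#' dimensions.
#'
#' @name data_model
NULL

MODALITIES <- c("A", "V", "T")

SCALE_RANGE <- list(BDI = c(0, 63), PHQ8 = c(0, 24))

#' Construct and validate a session sample
#'
#' @param session_id character scalar, unique within a cohort.
#' @param features named list of numeric matrices, names a subset of
#'   `c("A","V","T")`, all with identical row counts (rows = utterances).
#' @param label numeric severity score within the scale range.
#' @param scale `"BDI"` (range 0-63) or `"PHQ8"` (range 0-24).
#' @return An object of class `mignn_session`.
#' @export
session_sample <- function(session_id, features, label, scale = c("PHQ8", "BDI")) {
  scale <- match.arg(scale)
  if (!is.character(session_id) || length(session_id) != 1L || !nzchar(session_id))
    stopf("session_id must be a non-empty string")
  if (!is.list(features) || length(features) == 0L)
    stopf("session '%s': at least one modality must be present", session_id)
  mods <- names(features)
  if (is.null(mods) || !all(mods %in% MODALITIES) || anyDuplicated(mods))
    stopf("session '%s': feature names must be a subset of {A, V, T}", session_id)
  features <- lapply(features, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  ns <- vapply(features, nrow, integer(1))
  if (any(ns < 1L))
    stopf("session '%s': empty feature matrix", session_id)
  if (length(unique(ns)) != 1L)
    stopf("session '%s': utterance counts differ across modalities (%s)",
          session_id, paste(ns, collapse = " vs "))
  if (!all(vapply(features, function(m) all(is.finite(m)), logical(1))))
    stopf("session '%s': non-finite feature values", session_id)
  rng <- SCALE_RANGE[[scale]]
  if (!is.numeric(label) || length(label) != 1L || !is.finite(label) ||
      label < rng[1] || label > rng[2])
    stopf("session '%s': label %s outside %s range [%g, %g]",
          session_id, format(label), scale, rng[1], rng[2])
  structure(
    list(session_id = session_id,
         features = features[MODALITIES[MODALITIES %in% mods]],
         n_utterances = ns[[1]],
         label = as.numeric(label),
         scale = scale),
    class = "mignn_session")
}

#' @export
print.mignn_session <- function(x, ...) {
  dims <- vapply(x$features, ncol, integer(1))
  cat(sprintf("<mignn_session> %s: n=%d utterances, %s=%s, modalities %s\n",
              x$session_id, x$n_utterances, x$scale, format(x$label),
              paste(sprintf("%s(%d)", names(dims), dims), collapse = " ")))
  invisible(x)
}

#' Validate a cohort of sessions
#'
#' Checks uniqueness of session ids, a uniform modality set, uniform
#' per-modality feature dimensions and a uniform scale across the cohort.
#'
#' @param samples list of [session_sample()] objects.
#' @return The cohort, invisibly, with class `mignn_cohort`.
#' @export
as_cohort <- function(samples) {
  if (!length(samples)) {
    return(structure(list(), class = "mignn_cohort"))
  }
  stopifnot(all(vapply(samples, inherits, logical(1), "mignn_session")))
  ids <- vapply(samples, `[[`, character(1), "session_id")
  if (anyDuplicated(ids))
    stopf("duplicate session ids: %s", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  modsets <- lapply(samples, function(s) names(s$features))
  if (length(unique(vapply(modsets, paste, character(1), collapse = ","))) != 1L)
    stopf("modality set differs across sessions")
  scales <- unique(vapply(samples, `[[`, character(1), "scale"))
  if (length(scales) != 1L)
    stopf("mixed label scales in one cohort: %s", paste(scales, collapse = ", "))
  for (m in modsets[[1]]) {
    dms <- vapply(samples, function(s) ncol(s$features[[m]]), integer(1))
    if (length(unique(dms)) != 1L)
      stopf("modality %s: feature dimension differs across sessions (%s)",
            m, paste(unique(dms), collapse = " vs "))
  }
  structure(samples, class = "mignn_cohort")
}

#' @export
print.mignn_cohort <- function(x, ...) {
  if (!length(x)) {
    cat("<mignn_cohort> empty\n"); return(invisible(x))
  }
  ns <- vapply(x, `[[`, integer(1), "n_utterances")
  cat(sprintf("<mignn_cohort> %d sessions (%s), %d-%d utterances, modalities %s\n",
              length(x), x[[1]]$scale, min(ns), max(ns),
              paste(names(x[[1]]$features), collapse = "+")))
  invisible(x)
}

cohort_modalities <- function(cohort) names(cohort[[1]]$features)

cohort_dims <- function(cohort) {
  vapply(cohort[[1]]$features, ncol, integer(1))
}

#' Write a cohort to disk
#'
#' Emits one headerless comma-delimited matrix file per session per modality
#' (`<session_id>.<modality>.csv`, '.' decimal, UTF-8) and a JSON manifest
#' (`manifest.json`) listing session ids, labels, scale and relative paths.
#' Round-trips losslessly through [read_cohort()] at 1e-9 tolerance.
#'
#' @param samples a cohort (list of [session_sample()]).
#' @param out_dir output directory, created if needed.
#' @param split optional split tag recorded in the manifest
#'   (`"train"`, `"dev"` or `"test"`).
#' @param seed_note optional free-text provenance note.
#' @return Path to the written manifest, invisibly.
#' @export
write_cohort <- function(samples, out_dir, split = NULL, seed_note = NULL) {
  samples <- as_cohort(samples)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(samples, function(s) {
    paths <- setNames(
      sprintf("%s.%s.csv", s$session_id, names(s$features)),
      names(s$features))
    list(session_id = s$session_id, label = s$label, scale = s$scale,
         n_utterances = s$n_utterances, files = as.list(paths))
  })
  for (s in samples) {
    for (m in names(s$features)) {
      data.table::fwrite(
        data.table::as.data.table(s$features[[m]]),
        file.path(out_dir, sprintf("%s.%s.csv", s$session_id, m)),
        col.names = FALSE, sep = ",", dec = ".")
    }
  }
  manifest <- list(entries = entries)
  if (!is.null(split)) manifest$split <- match.arg(split, c("train", "dev", "test"))
  if (!is.null(seed_note)) manifest$seed_note <- as.character(seed_note)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path)
}

#' Read a cohort from a manifest
#'
#' Loads the JSON manifest written by [write_cohort()] (or assembled by hand
#' to the same schema) and the per-session feature matrices it references,
#' validating row counts across modalities, uniform dimensions across the
#' cohort and label ranges.  Utterance order is preserved: row *i* of a file
#' is utterance *i*.
#'
#' @param manifest_path path to `manifest.json`.
#' @return An `mignn_cohort` in manifest order.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stopf("manifest not found: %s", manifest_path)
  manifest <- jsonlite::read_json(manifest_path)
  base <- dirname(manifest_path)
  samples <- lapply(manifest$entries, function(e) {
    feats <- lapply(e$files, function(rel) {
      fp <- file.path(base, rel)
      if (!file.exists(fp))
        stopf("session '%s': feature file missing: %s", e$session_id, fp)
      as.matrix(data.table::fread(fp, header = FALSE, sep = ","))
    })
    names(feats) <- names(e$files)
    feats <- lapply(feats, function(m) { dimnames(m) <- NULL; m })
    session_sample(e$session_id, feats, e$label, e$scale)
  })
  as_cohort(samples)
}

cohort_labels <- function(cohort) vapply(cohort, `[[`, numeric(1), "label")

cohort_ids <- function(cohort) vapply(cohort, `[[`, character(1), "session_id")
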