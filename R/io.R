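# File formats: 3-column profile text (the interchange format for
# experimental data), PDB bead models, ensemble manifests and dataset
# snapshots.

#' Write a SWAXS profile as 3-column text
#'
#' Columns: q (inverse Angstrom), intensity, and sigma when present.
#' Header/comment lines are prefixed with `#`. Values are written at full
#' float precision so a write/read round trip is lossless.
#'
#' @param profile A `swaxs_profile`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  has_sigma <- !all(is.na(profile$sigma))
  hdr <- c(sprintf("# conformation: %s", attr(profile, "conformation_id") %||% NA),
           sprintf("# condition: %s", attr(profile, "condition") %||% NA),
           if (has_sigma) "# q intensity sigma" else "# q intensity")
  body <- if (has_sigma) {
    sprintf("%.17g %.17g %.17g", profile$q, profile$intensity, profile$sigma)
  } else {
    sprintf("%.17g %.17g", profile$q, profile$intensity)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SWAXS profile from 2- or 3-column text
#'
#' Whitespace- or comma-separated numeric text with `#` comment lines.
#' Two columns give a profile without errors (on which noisy inference
#' fails loudly); a third column is read as per-point sigma. Non-monotone
#' q, non-finite values or negative sigma raise a parse error naming the
#' offending line.
#'
#' @param path Input file path.
#' @return A `swaxs_profile`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) abort(sprintf("%s: no data lines.", path))
  parsed <- lapply(idx, function(i) {
    f <- strsplit(trimws(gsub(",", " ", lines[i])), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(v) < 2 || length(v) > 3 || any(is.na(v)) || any(!is.finite(v))) {
      abort(sprintf("%s line %d: expected 2 or 3 finite numeric columns.", path, i))
    }
    v
  })
  ncols <- unique(lengths(parsed))
  if (length(ncols) != 1) abort(sprintf("%s: inconsistent column counts.", path))
  m <- do.call(rbind, parsed)
  q <- m[, 1]
  bad <- which(diff(q) <= 0)
  if (length(bad)) {
    abort(sprintf("%s line %d: q values must be strictly increasing.", path, idx[bad[1] + 1]))
  }
  sigma <- if (ncols == 3) m[, 3] else NA_real_
  if (ncols == 3 && any(sigma < 0)) {
    abort(sprintf("%s line %d: negative sigma.", path, idx[which(sigma < 0)[1]]))
  }
  new_profile(q, m[, 2], sigma, condition = "experimental")
}

#' Write a duplex bead model as a PDB file
#'
#' One pseudo-atom per bead. Bead kinds are encoded in the atom name
#' (`P`, `S`, `B`), the strand in the chain id (`A`, `B`), and the bead
#' electron count in the B-factor column.
#'
#' @param model A `duplex_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_duplex_pdb <- function(model, path) {
  b <- model$beads
  elety <- c(phosphate = "P", sugar = "S", base = "B")[b$bead]
  seqs <- strsplit(model$sequence, "")
  resid <- ifelse(b$strand == 1L, seqs[[1]][b$residue], seqs[[2]][b$residue])
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(b[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(b)),
    resno = b$residue,
    resid = resid,
    eleno = seq_len(nrow(b)),
    elety = elety,
    chain = c("A", "B")[b$strand],
    o = rep(1, nrow(b)),
    b = b$electrons
  )
  invisible(path)
}

#' Read a duplex bead model from a PDB file
#'
#' Inverse of [write_duplex_pdb()]. The latent helical parameters are not
#' recoverable from a file; the returned model carries geometry only.
#'
#' @param path PDB file path.
#' @param conformation_id Id to attach; defaults to the file name.
#' @return A `duplex_model`.
#' @export
read_duplex_pdb <- function(path, conformation_id = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  bead_of <- c(P = "phosphate", S = "sugar", B = "base")
  kinds <- bead_of[trimws(at$elety)]
  if (any(is.na(kinds))) abort(sprintf("%s: unrecognized bead atom names.", path))
  strand <- match(trimws(at$chain), c("A", "B"))
  if (any(is.na(strand))) abort(sprintf("%s: chains must be A and B.", path))
  beads <- tibble(strand = as.integer(strand),
                  residue = as.integer(at$resno),
                  bead = unname(kinds),
                  x = at$x, y = at$y, z = at$z,
                  electrons = at$b)
  if (nrow(beads) != 72) {
    abort(sprintf("%s: expected 72 beads, found %d.", path, nrow(beads)))
  }
  s1 <- paste(at$resid[strand == 1 & kinds == "base"][order(at$resno[strand == 1 & kinds == "base"])],
              collapse = "")
  s2 <- paste(at$resid[strand == 2 & kinds == "base"][order(at$resno[strand == 2 & kinds == "base"])],
              collapse = "")
  structure(list(conformation_id = conformation_id %||% basename(path),
                 sequence = c(s1, s2),
                 beads = beads,
                 latent_params = NULL,
                 strand_phase_deg = NA_real_),
            class = "duplex_model")
}

#' Export a dataset for inspection
#'
#' Writes a single CSV with one row per profile: conformation id, condition,
#' split tag, the five labels, and the log10 intensities in q columns. An
#' RDS snapshot of the full `swaxs_dataset` object (the binary container
#' used by the pipeline) is written alongside when `rds = TRUE`.
#'
#' @param dataset A `swaxs_dataset`.
#' @param path CSV output path.
#' @param rds Also write `<path>.rds`.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path, rds = FALSE) {
  wide <- dplyr::bind_cols(
    dataset$labels,
    tibble(split = dataset$split %||% NA_character_),
    as_tibble(dataset$features)
  )
  utils::write.csv(wide, path, row.names = FALSE)
  if (rds) saveRDS(dataset, paste0(path, ".rds"))
  invisible(path)
}

#' Save / load a trained model bundle
#'
#' A bundle directory holds the serialized booster (`model.ubj`), the q
#' grid (`qgrid.txt`), and a JSON report with the descriptor, task,
#' configuration, metrics and best iteration.
#'
#' @param model A `waxs_model`.
#' @param dir Bundle directory (created if needed).
#' @return `dir` (save) or a `waxs_model` (load), invisibly for save.
#' @export
save_model_bundle <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  xgboost::xgb.save(model$booster, file.path(dir, "model.ubj"))
  writeLines(sprintf("%.17g", model$qgrid), file.path(dir, "qgrid.txt"))
  report <- list(descriptor = model$descriptor, task = model$task,
                 config = unclass(model$config),
                 metrics = model$metrics,
                 test_score = model$test_score,
                 best_iteration = model$best_iteration,
                 n_features = model$n_features)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(dir) {
  booster <- xgboost::xgb.load(file.path(dir, "model.ubj"))
  rep <- jsonlite::read_json(file.path(dir, "report.json"), simplifyVector = TRUE)
  qgrid <- as.numeric(readLines(file.path(dir, "qgrid.txt")))
  structure(list(booster = booster, descriptor = rep$descriptor,
                 task = rep$task,
                 qgrid = qgrid,
                 config = do.call(training_config, as.list(rep$config)),
                 metrics = as_tibble(rep$metrics),
                 test_score = rep$test_score,
                 test_label_variance = NA_real_,
                 best_iteration = rep$best_iteration,
                 n_features = rep$n_features),
            class = "waxs_model")
}
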