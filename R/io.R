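# Persistence: every artefact is written as delimited text plus a JSON
# manifest carrying the configuration and seeds needed to reproduce it
# exactly. Writers refuse to overwrite an existing output unless `force`.

pkg_version_string <- function() {
  as.character(utils::packageVersion("pipespace"))
}

check_outdir <- function(dir, marker, force) {
  if (file.exists(file.path(dir, marker)) && !force) {
    abort(sprintf("Output already exists in '%s'; use force = TRUE to overwrite.", dir))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
}

write_manifest <- function(manifest, path) {
  manifest$package_version <- pkg_version_string()
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

# Full-precision delimited writers: doubles are serialised with 17
# significant digits so round-trips are bit-faithful.
format_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}

write_matrix_tsv <- function(m, path) {
  txt <- apply(m, 1L, function(row) paste(format_full(row), collapse = "\t"))
  writeLines(txt, path)
}

write_table_tsv <- function(df, path) {
  df <- as.data.frame(df)
  cols <- lapply(df, format_full)
  txt <- c(paste(names(df), collapse = "\t"),
           do.call(paste, c(cols, sep = "\t")))
  writeLines(txt, path)
}

read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                              colClasses = "numeric"))
}

#' Write a synthetic cohort to disk
#'
#' One delimited-text matrix per subject per variant, plus a JSON manifest
#' (subject ids, targets, splits, communities, parcellations, config, seed).
#'
#' @param cohort A `subject_cohort`.
#' @param dir Output directory.
#' @param force Overwrite an existing cohort.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, force = FALSE) {
  check_outdir(dir, "cohort_manifest.json", force)
  for (v in names(cohort$variants)) {
    vdir <- file.path(dir, v)
    dir.create(vdir, showWarnings = FALSE)
    for (s in names(cohort$variants[[v]])) {
      write_matrix_tsv(cohort$variants[[v]][[s]],
                       file.path(vdir, paste0(s, ".tsv")))
    }
  }
  subjects_out <- cohort$subjects
  # doubles go through the JSON manifest as %.17g strings: jsonlite's
  # numeric serialisation is limited to 15 significant digits, which would
  # break bit-faithful round-trips
  subjects_out$target <- format_full(subjects_out$target)
  manifest <- list(
    subjects = subjects_out,
    variant_labels = names(cohort$variants),
    communities = cohort$communities,
    signal_edges = as.data.frame(cohort$signal_edges),
    parcellations = cohort$parcellations,
    config = unclass(cohort$config)
  )
  write_manifest(manifest, file.path(dir, "cohort_manifest.json"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir Cohort directory.
#' @return A `subject_cohort`.
#' @export
read_cohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "cohort_manifest.json"),
                             simplifyVector = TRUE)
  subjects <- as_tibble(man$subjects)
  subjects$target <- as.numeric(subjects$target)
  if (!"split" %in% names(subjects)) subjects$split <- NA_character_
  subjects$split[subjects$split %in% c("", "NA")] <- NA_character_
  variants <- lapply(man$variant_labels, function(v) {
    mats <- lapply(subjects$subject_id, function(s) {
      read_matrix_tsv(file.path(dir, v, paste0(s, ".tsv")))
    })
    names(mats) <- subjects$subject_id
    mats
  })
  names(variants) <- man$variant_labels
  cfg <- man$config
  config <- do.call(cohort_config, cfg[setdiff(names(cfg), character(0))])
  parc <- if (!is.null(man$parcellations) && length(man$parcellations)) {
    lapply(man$parcellations, as.integer)
  }
  structure(
    list(subjects = subjects, variants = variants,
         communities = as.integer(man$communities),
         signal_edges = as.matrix(man$signal_edges),
         parcellations = parc, config = config),
    class = "subject_cohort"
  )
}

#' Write a similarity table (+ manifest) to disk
#' @param table A `similarity_table`.
#' @param dir Output directory.
#' @param force Overwrite existing output.
#' @return `dir`, invisibly.
#' @export
write_similarity_table <- function(table, dir, force = FALSE) {
  check_outdir(dir, "similarity_manifest.json", force)
  write_matrix_tsv(table$matrix, file.path(dir, "similarity.tsv"))
  write_manifest(
    list(pipeline_id = table$pipeline_id, pairs = table$pairs,
         subject_id = table$subject_id),
    file.path(dir, "similarity_manifest.json"))
  invisible(dir)
}

#' Read a similarity table written by [write_similarity_table()]
#' @param dir Directory.
#' @return A `similarity_table`.
#' @export
read_similarity_table <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "similarity_manifest.json"),
                             simplifyVector = TRUE)
  structure(
    list(matrix = read_matrix_tsv(file.path(dir, "similarity.tsv")),
         pipeline_id = as.integer(man$pipeline_id),
         pairs = as_tibble(man$pairs),
         subject_id = man$subject_id),
    class = "similarity_table"
  )
}

#' Write an embedded space (+ manifest) to disk
#' @param space An `embedded_space`.
#' @param dir Output directory.
#' @param force Overwrite existing output.
#' @return `dir`, invisibly.
#' @export
write_embedding <- function(space, dir, force = FALSE) {
  check_outdir(dir, "embedding_manifest.json", force)
  write_table_tsv(space, file.path(dir, "embedding.tsv"))
  write_manifest(
    list(method = attr(space, "method"), seed = attr(space, "seed"),
         stress = attr(space, "stress"), params = attr(space, "params")),
    file.path(dir, "embedding_manifest.json"))
  invisible(dir)
}

#' Read an embedding written by [write_embedding()]
#' @param dir Directory.
#' @return An `embedded_space`.
#' @export
read_embedding <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "embedding_manifest.json"),
                             simplifyVector = TRUE)
  tab <- as_tibble(utils::read.table(file.path(dir, "embedding.tsv"),
                                     sep = "\t", header = TRUE))
  structure(tab, method = man$method, seed = man$seed, stress = man$stress,
            params = man$params, class = c("embedded_space", class(tab)))
}

#' Write a search trace (+ run manifest) to disk
#' @param trace A `search_trace`.
#' @param dir Output directory.
#' @param force Overwrite existing output.
#' @return `dir`, invisibly.
#' @export
write_trace <- function(trace, dir, force = FALSE) {
  check_outdir(dir, "run_manifest.json", force)
  write_table_tsv(trace$trace, file.path(dir, "trace.tsv"))
  write_manifest(
    list(config = unclass(trace$config), search_seed = trace$search_seed,
         gp_theta = trace$gp$theta,
         gp_log_marginal_likelihood = trace$gp$log_marginal_likelihood),
    file.path(dir, "run_manifest.json"))
  invisible(dir)
}

#' Read a trace table written by [write_trace()]
#'
#' The tabular log round-trips; the fitted GP is reconstructed by re-running
#' the search with the manifest's seeds if needed.
#' @param dir Directory.
#' @return List with `trace` tibble and `manifest`.
#' @export
read_trace <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "run_manifest.json"),
                             simplifyVector = TRUE)
  tab <- as_tibble(utils::read.table(file.path(dir, "trace.tsv"),
                                     sep = "\t", header = TRUE))
  list(trace = tab, manifest = man)
}
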