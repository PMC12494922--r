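#' Write a cohort to a directory of plain-text files
#'
#' One tab-delimited matrix file per subject (`<id>_fc.tsv`), the subject
#' table as `subjects.csv` with fixed columns (id, age, sex,
#' education_years, domain, group, expertise_score), and the generator
#' provenance as `provenance.txt`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- cohort$subjects[, c("id", "age", "sex", "education_years",
                              "domain", "group", "expertise_score")]
  utils::write.csv(meta, file.path(dir, "subjects.csv"), row.names = FALSE)
  for (i in seq_along(cohort$matrices)) {
    fn <- file.path(dir, sprintf("%s_%s_fc.tsv", cohort$subjects$id[i],
                                 cohort$subjects$group[i]))
    utils::write.table(cohort$matrices[[i]]$values, fn, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  writeLines(utils::capture.output(utils::str(cohort$provenance)),
             file.path(dir, "provenance.txt"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory holding `subjects.csv` and one `*_fc.tsv` per
#'   subject.
#' @return A `cohort` object (provenance notes only the source directory).
#' @export
read_cohort <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "subjects.csv"),
                          stringsAsFactors = FALSE)
  matrices <- lapply(seq_len(nrow(meta)), function(i) {
    fn <- file.path(dir, sprintf("%s_%s_fc.tsv", meta$id[i], meta$group[i]))
    v <- as.matrix(utils::read.table(fn, sep = "\t"))
    dimnames(v) <- NULL
    fc_matrix(v, "correlation")
  })
  structure(
    list(subjects = meta, matrices = matrices,
         provenance = list(source = dir)),
    class = "cohort"
  )
}

#' Write a structural connectome as delimited text
#'
#' Weights as a tab-delimited matrix, coordinates (with hub flags) as CSV.
#'
#' @param connectome A [structural_connectome()].
#' @param weights_file,coords_file Output paths.
#' @return Invisibly `NULL`.
#' @export
write_connectome <- function(connectome, weights_file, coords_file) {
  stopifnot(inherits(connectome, "structural_connectome"))
  utils::write.table(connectome$weights, weights_file, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  coords <- data.frame(region_label = connectome$region_labels,
                       x = connectome$coordinates[, 1],
                       y = connectome$coordinates[, 2],
                       z = connectome$coordinates[, 3],
                       hub = connectome$hub_mask)
  utils::write.csv(coords, coords_file, row.names = FALSE)
  invisible(NULL)
}

#' Read a structural connectome written by [write_connectome()]
#'
#' @param weights_file,coords_file Input paths.
#' @return A [structural_connectome()].
#' @export
read_connectome <- function(weights_file, coords_file) {
  w <- as.matrix(utils::read.table(weights_file, sep = "\t"))
  dimnames(w) <- NULL
  coords <- utils::read.csv(coords_file)
  xyz <- unname(as.matrix(coords[, c("x", "y", "z")]))
  structural_connectome(w, xyz, as.logical(coords$hub),
                        coords$region_label)
}

#' Write a regional map as two-column CSV
#'
#' @param map A [regional_map()].
#' @param file Output path.
#' @return Invisibly `NULL`.
#' @export
write_regional_map <- function(map, file) {
  stopifnot(inherits(map, "regional_map"))
  utils::write.csv(data.frame(region_label = map$region_labels,
                              value = map$values),
                   file, row.names = FALSE)
  invisible(NULL)
}

#' Read a regional map written by [write_regional_map()]
#'
#' @param file Input path.
#' @param name Map name to attach.
#' @return A [regional_map()].
#' @export
read_regional_map <- function(file, name = "map") {
  d <- utils::read.csv(file)
  regional_map(d$value, name, d$region_label)
}
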