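# Plain-text readers and writers for the trial file formats: genotype
# dosage matrices (tab-separated or PLINK .raw dialect), 3-column
# pedigrees, phenotype tables and marker maps. Writers are
# deterministic: stable column order, floats at 10 significant digits.

fmt_num <- function(x) formatC(x, format = "g", digits = 10)

#' Read a genotype dosage matrix
#'
#' `"tsv-dosage"` files have an `id` column then one column per marker;
#' `"plink-raw"` files carry the six PLINK leading columns
#' (`FID IID PAT MAT SEX PHENOTYPE`) before the markers, whose names may
#' end in a counted-allele suffix (`_A` etc.) that is stripped. Values
#' must be complete dosages in {0, 1, 2}; anything else is rejected with
#' its row number.
#'
#' @param path file path.
#' @param dialect `"tsv-dosage"` (default) or `"plink-raw"`.
#' @return Integer matrix, individuals x markers, with id rownames.
#' @export
read_genotypes <- function(path, dialect = c("tsv-dosage", "plink-raw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = if (dialect == "tsv-dosage") "\t" else "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("no records in ", path, call. = FALSE)
  if (dialect == "tsv-dosage") {
    ids <- as.character(df[[1L]])
    G <- df[, -1L, drop = FALSE]
  } else {
    need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(need %in% names(df)[1:6])) {
      stop("plink-raw file lacks the six leading columns", call. = FALSE)
    }
    ids <- as.character(df[["IID"]])
    G <- df[, -(1:6), drop = FALSE]
    names(G) <- sub("_[ACGT012]$", "", names(G))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate individual id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  M <- as.matrix(G)
  suppressWarnings(storage.mode(M) <- "integer")
  bad <- which(is.na(M) | M < 0L | M > 2L, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-dosage value at row %d, marker '%s'",
                 bad[1L, 1L], colnames(M)[bad[1L, 2L]]), call. = FALSE)
  }
  rownames(M) <- ids
  M
}

#' Write a genotype dosage matrix
#'
#' @param G integer dosage matrix with id rownames and marker colnames.
#' @param path output path.
#' @param dialect `"tsv-dosage"` or `"plink-raw"` (PLINK leading columns
#'   filled with id / zeros).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path, dialect = c("tsv-dosage", "plink-raw")) {
  dialect <- match.arg(dialect)
  stopifnot(is.matrix(G), !is.null(rownames(G)), !is.null(colnames(G)))
  if (dialect == "tsv-dosage") {
    df <- data.frame(id = rownames(G), G, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    df <- data.frame(FID = rownames(G), IID = rownames(G), PAT = 0, MAT = 0,
                     SEX = 0, PHENOTYPE = -9, G, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write a 3-column pedigree
#'
#' Tab-separated `id`, `sire`, `dam` with `"0"` for unknown parents.
#' Reading validates and topologically orders the pedigree (children
#' after parents); cycles and orphan parent ids are rejected.
#'
#' @param path file path.
#' @return `read_pedigree()`: ordered pedigree data.frame.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L) stop("no records in ", path, call. = FALSE)
  if (!all(c("id", "sire", "dam") %in% names(df))) {
    stop("pedigree file must have columns id, sire, dam", call. = FALSE)
  }
  validate_pedigree(df)
}

#' @rdname read_pedigree
#' @param ped pedigree data.frame.
#' @export
write_pedigree <- function(ped, path) {
  ped <- validate_pedigree(ped)
  utils::write.table(ped, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a phenotype table
#'
#' Tab-separated `id`, `family`, `site`, `block`, `y`.
#'
#' @param path file path.
#' @return `read_phenotypes()`: phenotype data.frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no records in ", path, call. = FALSE)
  need <- c("id", "family", "site", "block", "y")
  if (!all(need %in% names(df))) {
    stop("phenotype file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$id)) {
    stop("duplicate phenotype id: ", df$id[duplicated(df$id)][1L],
         call. = FALSE)
  }
  if (any(!is.finite(df$y))) {
    stop(sprintf("non-numeric phenotype at row %d",
                 which(!is.finite(df$y))[1L]), call. = FALSE)
  }
  df[need]
}

#' @rdname read_phenotypes
#' @param pheno phenotype data.frame (`id`, `family`, `site`, `block`,
#'   `y`).
#' @export
write_phenotypes <- function(pheno, path) {
  need <- c("id", "family", "site", "block", "y")
  stopifnot(all(need %in% names(pheno)))
  out <- pheno[need]
  out$y <- fmt_num(out$y)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a marker map
#'
#' Tab-separated `marker`, `chromosome`, `position_cM`. Reading returns
#' a `genetic_map` whose chromosome lengths are the maxima of observed
#' positions (exact round-trip lengths are preserved through the
#' `length_cM` attribute column written by [write_map()]).
#'
#' @param path file path.
#' @return `read_map()`: a `genetic_map` object.
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no records in ", path, call. = FALSE)
  if (!all(c("marker", "chromosome", "position_cM") %in% names(df))) {
    stop("map file must have columns marker, chromosome, position_cM",
         call. = FALSE)
  }
  has_len <- "chromosome_length_cM" %in% names(df)
  chrs <- unique(df$chromosome)
  lens <- vapply(chrs, function(ch) {
    rows <- df$chromosome == ch
    if (has_len) df$chromosome_length_cM[rows][1L]
    else max(df$position_cM[rows])
  }, numeric(1))
  names(lens) <- chrs
  ord <- order(match(df$chromosome, chrs), df$position_cM)
  df <- df[ord, ]
  if (any(df$position_cM < 0) ||
      any(df$position_cM > lens[df$chromosome] + 1e-9)) {
    stop("marker positions outside chromosome bounds", call. = FALSE)
  }
  map <- list(chr_lengths = lens, marker = df$marker,
              chromosome = df$chromosome, position_cM = df$position_cM,
              total_length_cM = sum(lens), n_markers = nrow(df))
  class(map) <- "genetic_map"
  map
}

#' @rdname read_map
#' @param map a `genetic_map`.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "genetic_map"))
  df <- data.frame(marker = map$marker, chromosome = map$chromosome,
                   position_cM = fmt_num(map$position_cM),
                   chromosome_length_cM =
                     fmt_num(map$chr_lengths[map$chromosome]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a population's files as a simulated-trial bundle
#'
#' Writes `genotypes.tsv`, `pedigree.tsv`, `map.tsv` and, when
#' phenotypes are supplied, `phenotypes.tsv` into a directory, plus a
#' small `run_info.txt` provenance header (package version and seed if
#' given).
#'
#' @param pop a [simulate_population()] object.
#' @param dir output directory (created if missing).
#' @param phenotypes optional [simulate_phenotypes()] object or
#'   phenotype data.frame.
#' @param seed optional seed to record in the provenance header.
#' @return `dir`, invisibly.
#' @export
write_trial_bundle <- function(pop, dir, phenotypes = NULL, seed = NULL) {
  stopifnot(inherits(pop, "sim_population"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(pop$dosage, file.path(dir, "genotypes.tsv"))
  write_pedigree(pop$pedigree, file.path(dir, "pedigree.tsv"))
  write_map(pop$map, file.path(dir, "map.tsv"))
  if (!is.null(phenotypes)) {
    if (inherits(phenotypes, "sim_phenotypes")) phenotypes <- phenotypes$pheno
    write_phenotypes(phenotypes, file.path(dir, "phenotypes.tsv"))
  }
  writeLines(c(
    sprintf("package: conifergs %s",
            as.character(utils::packageVersion("conifergs"))),
    sprintf("design: %s", pop$design$kind),
    sprintf("seed: %s", if (is.null(seed)) "unrecorded" else seed),
    sprintf("written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  ), file.path(dir, "run_info.txt"))
  invisible(dir)
}
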