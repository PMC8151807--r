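# Text PED/MAP genotype interchange (space-separated, alleles A/B,
# missing "0"), plus CSV helpers for pedigrees and weight records.

#' Write genotypes as PLINK-style PED/MAP text
#'
#' One line per bull: family id (`FAM`), individual id, parent ids (0),
#' sex (0), phenotype (-9), then two allele columns per SNP with alleles
#' coded `A`/`B` and missing genotypes as `0 0`.  The `.map` file carries
#' chromosome, SNP name, genetic distance (0) and physical position.
#'
#' @param g `calf_genotypes`.
#' @param prefix output path without extension; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(g, prefix) {
  X <- g$dosage
  n <- nrow(X); m <- ncol(X)
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("BULL%05d", seq_len(n))
  a1 <- matrix("A", n, m); a2 <- matrix("A", n, m)
  a1[X == 0] <- "B"; a2[X <= 1] <- "B"
  a1[is.na(X)] <- "0"; a2[is.na(X)] <- "0"
  geno <- matrix("", n, 2L * m)
  geno[, seq(1, 2 * m, 2)] <- a1
  geno[, seq(2, 2 * m, 2)] <- a2
  lines <- cbind("FAM", ids, "0", "0", "0", "-9", geno)
  writeLines(apply(lines, 1, paste, collapse = " "),
             paste0(prefix, ".ped"))
  write.table(data.frame(g$map$chr, g$map$snp, 0, g$map$bp),
              paste0(prefix, ".map"), quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK-style PED/MAP text genotypes
#'
#' Counts `A` alleles per genotype, so dosage 2 means `A A`; a missing
#' allele (`0`) makes the genotype missing.
#'
#' @param prefix path without extension (expects `<prefix>.ped`,
#'   `<prefix>.map`).
#' @return A `calf_genotypes` object (without simulation truth fields).
#' @export
read_plink <- function(prefix) {
  map <- read.table(paste0(prefix, ".map"), header = FALSE,
                    col.names = c("chr", "snp", "cm", "bp"),
                    stringsAsFactors = FALSE)
  lines <- strsplit(readLines(paste0(prefix, ".ped")), " +")
  m <- nrow(map)
  X <- t(vapply(lines, function(fld) {
    al <- matrix(fld[-(1:6)], nrow = 2)
    d <- colSums(al == "A")
    d[al[1, ] == "0" | al[2, ] == "0"] <- NA_integer_
    as.integer(d)
  }, integer(m)))
  rownames(X) <- vapply(lines, `[`, character(1), 2)
  colnames(X) <- map$snp
  structure(list(dosage = X,
                 map = data.frame(snp = map$snp, chr = map$chr, bp = map$bp,
                                  stringsAsFactors = FALSE),
                 freq = colMeans(X, na.rm = TRUE) / 2),
            class = "calf_genotypes")
}

#' Write / read a pedigree as headered CSV (ISO-8601 dates)
#'
#' @param ped pedigree data frame.
#' @param path CSV path.
#' @return `write_pedigree`: the path, invisibly. `read_pedigree`: the
#'   pedigree, validated and sorted.
#' @export
write_pedigree <- function(ped, path) {
  write.csv(ped, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  ped <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!is.null(ped$birth_date)) ped$birth_date <- as.Date(ped$birth_date)
  if (!is.null(ped$multiple_birth))
    ped$multiple_birth <- as.logical(ped$multiple_birth)
  validate_and_sort(ped)
}

#' Write / read weight records as headered CSV
#'
#' @param records weight-record data frame.
#' @param path CSV path.
#' @return `write_records`: the path, invisibly. `read_records`: the table.
#' @export
write_records <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("weigh_date", "birth_date"))
    if (!is.null(rec[[col]])) rec[[col]] <- as.Date(rec[[col]])
  rec
}
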