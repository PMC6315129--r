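#' Read a genotype matrix from the simple TSV dialect
#'
#' Rows are subjects, the first column is `subject_id`, remaining columns
#' are SNP ids with additive codes 0/1/2 (empty or `NA` for missing).
#'
#' @param path TSV file path
#' @return numeric matrix with subject ids as rownames and SNP ids as
#'   colnames
#' @export
readGenotypesTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df))
    stop("genotype TSV must have a subject_id column")
  if (anyDuplicated(df$subject_id)) stop("duplicate subject ids")
  g <- as.matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
  storage.mode(g) <- "double"
  rownames(g) <- df$subject_id
  .checkGenotypes(g)
  g
}

#' Write a genotype matrix to the simple TSV dialect
#'
#' @param genotypes subjects x SNPs matrix with dimnames
#' @param path output TSV path
#' @return invisibly, `path`
#' @export
writeGenotypesTSV <- function(genotypes, path) {
  .checkGenotypes(genotypes)
  df <- data.frame(subject_id = rownames(genotypes), genotypes,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read PLINK text pedigree files (.ped/.map)
#'
#' Converts biallelic genotypes to additive minor-allele counts per SNP
#' (minor allele from the sample frequency; ties broken toward the
#' lexicographically smaller allele; `0 0` is missing).
#'
#' @param pedPath path to the `.ped` file
#' @param mapPath path to the `.map` file
#' @return `list(genotypes = subjects x SNPs additive matrix, map =
#'   data.frame(chr, snp, cm, pos), fam = data.frame of the six pedigree
#'   columns)`
#' @export
readPlinkPedMap <- function(pedPath, mapPath) {
  map <- utils::read.table(mapPath, header = FALSE,
                           col.names = c("chr", "snp", "cm", "pos"),
                           stringsAsFactors = FALSE)
  ped <- utils::read.table(pedPath, header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  nsnp <- nrow(map)
  if (ncol(ped) != 6 + 2 * nsnp)
    stop(".ped has ", ncol(ped), " columns; expected ", 6 + 2 * nsnp,
         " for ", nsnp, " SNPs")
  fam <- ped[, 1:6]
  names(fam) <- c("fid", "iid", "pat", "mat", "sex", "pheno")
  G <- matrix(NA_real_, nrow(ped), nsnp,
              dimnames = list(fam$iid, map$snp))
  for (j in seq_len(nsnp)) {
    a1 <- ped[[6 + 2 * j - 1]]
    a2 <- ped[[6 + 2 * j]]
    miss <- a1 == "0" | a2 == "0"
    alleles <- sort(unique(c(a1[!miss], a2[!miss])))
    if (!length(alleles)) next
    if (length(alleles) > 2)
      stop("SNP ", map$snp[j], " has more than two alleles")
    counts <- vapply(alleles,
                     function(a) sum(a1[!miss] == a) + sum(a2[!miss] == a),
                     numeric(1))
    minor <- alleles[which.min(counts)]  # which.min: first (lexicographic) tie-break
    G[!miss, j] <- (a1[!miss] == minor) + (a2[!miss] == minor)
  }
  list(genotypes = G, map = map, fam = fam)
}

#' Read a phenotype/covariate table
#'
#' TSV with a `subject_id` column plus score and covariate columns (e.g.
#' `age`, `sex`).
#'
#' @param path TSV file path
#' @return data.frame
#' @export
readPhenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df))
    stop("phenotype table must have a subject_id column")
  df
}
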