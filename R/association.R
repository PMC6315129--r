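#' Minor-allele carrier filter
#'
#' Removes SNPs whose minor allele is present in fewer than `minSubjects`
#' subjects. "Present in a subject" is read as carrier status (at least one
#' copy); `mode = "allele"` counts allele copies instead. The minor allele
#' is determined per SNP from the sample frequency; monomorphic SNPs are
#' always removed.
#'
#' @param genotypes subjects x SNPs matrix of additive codes 0/1/2 (NA for
#'   missing), with SNP ids as colnames
#' @param minSubjects minimum carrier (or allele) count (default 5)
#' @param mode `"carrier"` (default) or `"allele"`
#' @return the filtered genotype matrix (possibly with zero columns, with a
#'   warning)
#' @export
macFilter <- function(genotypes, minSubjects = 5,
                      mode = c("carrier", "allele")) {
  mode <- match.arg(mode)
  .checkGenotypes(genotypes)
  keep <- vapply(seq_len(ncol(genotypes)), function(j) {
    g <- genotypes[, j]
    g <- g[!is.na(g)]
    if (!length(g)) return(FALSE)
    if (mean(g) / 2 > 0.5) g <- 2 - g   # recode so g counts the minor allele
    cnt <- if (mode == "carrier") sum(g >= 1) else sum(g)
    cnt >= minSubjects
  }, logical(1))
  if (!any(keep)) warning("minor-allele filter removed every SNP")
  genotypes[, keep, drop = FALSE]
}

.checkGenotypes <- function(g) {
  if (!is.matrix(g)) stop("genotypes must be a subjects x SNPs matrix")
  v <- g[!is.na(g)]
  if (length(v) && !all(v %in% c(0, 1, 2)))
    stop("genotype codes must be 0, 1, 2 or NA")
  invisible(TRUE)
}

#' Genotype principal components (ancestry covariates)
#'
#' Top-k principal component scores of the column-standardized genotype
#' matrix (missing codes mean-imputed, monomorphic SNPs dropped). The sign
#' of each component is fixed by forcing its largest-magnitude loading
#' positive, so results are deterministic.
#'
#' @param genotypes subjects x SNPs matrix of additive codes
#' @param k number of components (default 4)
#' @return subjects x k matrix of PC scores
#' @export
genotypePCs <- function(genotypes, k = 4) {
  stopifnot(k >= 1)
  .checkGenotypes(genotypes)
  Z <- apply(genotypes, 2, function(g) {
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    g
  })
  sds <- apply(Z, 2, stats::sd)
  Z <- scale(Z[, sds > 0, drop = FALSE])
  sv <- svd(Z)
  rank <- sum(sv$d > sv$d[1] * 1e-8)
  if (k > rank)
    stop("k = ", k, " exceeds the rank (", rank, ") of the genotype matrix")
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  for (j in seq_len(k)) {
    load <- sv$v[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Single-SNP linear association test
#'
#' Ordinary least squares of the phenotype score on
#' `[intercept, genotype, covariates]`, with a two-sided t-test on the
#' genotype coefficient. Subjects with a missing genotype (or any missing
#' regressor) are dropped for that SNP.
#'
#' @param phenotype numeric score vector
#' @param genotype additive genotype codes (0/1/2, NA allowed)
#' @param covariates optional numeric matrix or data.frame of covariates
#'   (e.g. age, sex, ancestry PCs)
#' @return `list(beta, se, statistic, p.value, n, df, coefficients)` for
#'   the genotype term; `coefficients` is the full OLS table
#' @export
linearAssoc <- function(phenotype, genotype, covariates = NULL) {
  X <- cbind(`(Intercept)` = 1, g = as.numeric(genotype))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  y <- as.numeric(phenotype)
  cc <- stats::complete.cases(X, y)
  X <- X[cc, , drop = FALSE]
  y <- y[cc]
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1) stop("too few complete cases (", n, ") for ", p,
                       " regression terms")
  fit <- .olsFit(X, y)
  c(fit$table["g", ], list(n = n, df = n - p, coefficients = fit$table))
}

.olsFit <- function(X, y) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("collinear design: column(s) ", paste(bad, collapse = ", "),
         " are linearly dependent on the others")
  }
  beta <- qr.coef(qx, y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  Rm <- qr.R(qx)
  Vp <- chol2inv(Rm)
  V <- matrix(0, ncol(X), ncol(X))
  piv <- qx$pivot
  V[piv, piv] <- Vp
  se <- sqrt(sigma2 * diag(V))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  tab <- data.frame(beta = beta, se = se, statistic = tval, p.value = pval)
  rownames(tab) <- colnames(X)
  list(table = tab, sigma2 = sigma2, df = df)
}

#' Genome-wide association scan over one or more phenotype scores
#'
#' Applies the minor-allele carrier filter, computes genotype PCs, runs the
#' per-SNP linear model with age, sex and the PCs as covariates for every
#' phenotype, and adjusts p-values with Benjamini-Hochberg globally over
#' the pooled tests of all phenotypes.
#'
#' @param phenotypes named list of numeric score vectors (or a single
#'   vector)
#' @param genotypes subjects x SNPs matrix of additive codes with SNP id
#'   colnames
#' @param age,sex numeric covariate vectors (sex coded 0/1)
#' @param snpInfo optional data.frame with columns `snp`, `chr`, `pos`
#'   aligned to the genotype columns
#' @param nPCs number of ancestry PCs (default 4)
#' @param macMin minor-allele carrier threshold (default 5; see
#'   [macFilter()])
#' @return data.frame with columns `PHENO, SNP, CHR, POS, BETA, SE, T, P,
#'   P_FDR`
#' @export
associationScan <- function(phenotypes, genotypes, age = NULL, sex = NULL,
                            snpInfo = NULL, nPCs = 4, macMin = 5) {
  if (!is.list(phenotypes)) phenotypes <- list(score = phenotypes)
  if (is.null(names(phenotypes)))
    names(phenotypes) <- paste0("score", seq_along(phenotypes))
  G <- macFilter(genotypes, minSubjects = macMin)
  covs <- NULL
  if (!is.null(age)) covs <- cbind(covs, age = as.numeric(age))
  if (!is.null(sex)) covs <- cbind(covs, sex = as.numeric(sex))
  if (nPCs > 0 && ncol(G) > nPCs) covs <- cbind(covs, genotypePCs(G, nPCs))
  ids <- colnames(G)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(G)))
  if (is.null(snpInfo))
    snpInfo <- data.frame(snp = ids, chr = NA_integer_, pos = NA_integer_)
  info <- snpInfo[match(ids, snpInfo$snp), , drop = FALSE]
  out <- do.call(rbind, lapply(names(phenotypes), function(ph) {
    y <- phenotypes[[ph]]
    rows <- lapply(seq_len(ncol(G)), function(j) {
      fit <- linearAssoc(y, G[, j], covs)
      data.frame(PHENO = ph, SNP = ids[j], CHR = info$chr[j],
                 POS = info$pos[j], BETA = fit$beta, SE = fit$se,
                 T = fit$statistic, P = fit$p.value,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  rownames(out) <- NULL
  out$P_FDR <- bhAdjust(out$P)   # global across all phenotypes
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_i = min_(j >= i) p_(j) * m / j`, clipped at 1 — applied to the pooled
#' p-value vector (globally over phenotypes in [associationScan()]).
#'
#' @param p numeric vector of raw p-values in (0, 1]
#' @return adjusted p-values, elementwise >= the raw values
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Age and sex association tests for a phenotype score
#'
#' Pearson correlation (t approximation) for the continuous age covariate;
#' Kendall tau-b with the normal approximation for the dichotomous sex
#' covariate, which does not assume normality.
#'
#' @param scores numeric phenotype score vector
#' @param age numeric ages
#' @param sex 0/1 coded sex (the signs of tau and beta depend on the
#'   coding)
#' @return data.frame with rows `pearson_age` and `kendall_sex` and columns
#'   `estimate`, `statistic`, `p.value`
#' @export
covariateTests <- function(scores, age, sex) {
  if (length(scores) < 3) stop("at least 3 observations required")
  for (v in list(scores = scores, age = age, sex = sex)) {
    if (stats::sd(as.numeric(v)) == 0)
      stop("constant input vector: correlation undefined")
  }
  pe <- stats::cor.test(scores, age, method = "pearson")
  ke <- stats::cor.test(scores, as.numeric(sex), method = "kendall",
                        exact = FALSE)
  data.frame(test = c("pearson_age", "kendall_sex"),
             estimate = c(unname(pe$estimate), unname(ke$estimate)),
             statistic = c(unname(pe$statistic), unname(ke$statistic)),
             p.value = c(pe$p.value, ke$p.value),
             stringsAsFactors = FALSE)
}

#' Ranked association table with significance flags
#'
#' Sorts association results by p-value and flags each SNP as
#' `significant` (genome-wide), `suggestive`, or `ns`.
#'
#' @param results data.frame from [associationScan()]
#' @param significance genome-wide threshold (default 5e-8)
#' @param suggestive suggestive threshold (default 1e-5)
#' @return the sorted data.frame with an added `level` column
#' @export
manhattanTable <- function(results, significance = 5e-8,
                           suggestive = 1e-5) {
  if (!nrow(results)) {
    results$level <- character(0)
    return(results)
  }
  results <- results[order(results$P), , drop = FALSE]
  results$level <- ifelse(results$P < significance, "significant",
                          ifelse(results$P < suggestive, "suggestive", "ns"))
  rownames(results) <- NULL
  results
}

#' Manhattan plot of association results
#'
#' Base-graphics -log10(p) by genomic order with the genome-wide and
#' suggestive threshold lines.
#'
#' @inheritParams manhattanTable
#' @param main plot title
#' @return invisibly, the plotted data.frame
#' @export
manhattanPlot <- function(results, significance = 5e-8, suggestive = 1e-5,
                          main = "Association scan") {
  stopifnot(nrow(results) > 0)
  ord <- order(results$CHR, results$POS)
  df <- results[ord, , drop = FALSE]
  x <- seq_len(nrow(df))
  col <- if (all(is.na(df$CHR))) "grey30" else
    c("grey30", "steelblue")[(df$CHR %% 2) + 1]
  graphics::plot(x, -log10(df$P), pch = 20, col = col,
                 xlab = "SNP (genomic order)",
                 ylab = expression(-log[10](italic(p))), main = main)
  graphics::abline(h = -log10(significance), col = "red")
  graphics::abline(h = -log10(suggestive), col = "blue")
  invisible(df)
}
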