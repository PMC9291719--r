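# Synthetic GWAS-like cohorts: annotations, genotypes with LD blocks and
# population structure, and binary endpoints with heterogeneous case subgroups.

#' Simulate a gene/enhancer/SNP-score annotation fixture
#'
#' Builds the annotation universe the feature-set construction consumes: a set
#' of druggable seed genes, each with a number of connected genes, one putative
#' enhancer per gene, and a per-SNP score table (MAF, imputation info, CADD,
#' GWAVA, TraP). A configurable fraction of SNPs is given scores passing the
#' functionality filter (CADD >= 10 or GWAVA >= 0.5 or TraP >= 0.459); all SNPs
#' pass the MAF/info QC by construction so the two filters can be tested
#' independently.
#'
#' Coordinates are BED-style 0-based half-open. Genes are laid out without
#' overlap on one chromosome per druggable gene, with the enhancer placed in
#' the intergenic gap downstream of its gene.
#'
#' @param n_druggable number of druggable seed genes.
#' @param connected_per_druggable connected genes per druggable gene.
#' @param snps_per_gene SNPs placed in each gene (80\% in the extended body,
#'   the rest in its enhancer).
#' @param pass_fraction fraction of SNPs whose scores pass the functionality
#'   filter.
#' @param maf_range range of simulated minor allele frequencies.
#' @param seed RNG seed.
#' @return an object of class `annotation_fixture`: a list with data frames
#'   `genes` (gene_id, chrom, start, end, strand, role, druggable_parent),
#'   `enhancers` (gene_id, chrom, start, end, tissue) and `snps` (snp_id,
#'   chrom, pos, maf, info, cadd, gwava, trap).
#' @export
simulate_annotations <- function(n_druggable = 2, connected_per_druggable = 3,
                                 snps_per_gene = 10, pass_fraction = 0.8,
                                 maf_range = c(0.05, 0.5), seed = 1) {
  stopifnot(n_druggable >= 1, connected_per_druggable >= 1, snps_per_gene >= 1,
            pass_fraction >= 0, pass_fraction <= 1)
  with_seed(seed, {
    gene_len <- 20000L
    gap <- 50000L
    genes <- list(); enhancers <- list(); snps <- list()
    tissues <- c("heart", "fat", "vascular")
    snp_counter <- 0L
    for (d in seq_len(n_druggable)) {
      chrom <- as.character(d)
      dg_id <- sprintf("DG%02d", d)
      ids <- c(dg_id, sprintf("CG%02d_%02d", d, seq_len(connected_per_druggable)))
      for (g in seq_along(ids)) {
        start <- 100000L + (g - 1L) * (gene_len + gap)
        end <- start + gene_len
        strand <- if (g %% 2L == 1L) "+" else "-"
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = ids[g], chrom = chrom, start = start, end = end,
          strand = strand, role = if (g == 1L) "druggable" else "connected",
          druggable_parent = if (g == 1L) NA_character_ else dg_id,
          stringsAsFactors = FALSE)
        enh_start <- end + 10000L
        enhancers[[length(enhancers) + 1L]] <- data.frame(
          gene_id = ids[g], chrom = chrom, start = enh_start,
          end = enh_start + 1000L, tissue = sample(tissues, 1L),
          stringsAsFactors = FALSE)
        n_body <- max(1L, round(0.8 * snps_per_gene))
        n_enh <- snps_per_gene - n_body
        pos <- c(sort(sample(start:(end - 1L), n_body)),
                 if (n_enh > 0L) sort(sample(enh_start:(enh_start + 999L), n_enh)))
        snps[[length(snps) + 1L]] <- data.frame(
          snp_id = sprintf("rs%06d", snp_counter + seq_along(pos)),
          chrom = chrom, pos = pos, stringsAsFactors = FALSE)
        snp_counter <- snp_counter + length(pos)
      }
    }
    genes <- do.call(rbind, genes)
    enhancers <- do.call(rbind, enhancers)
    snps <- do.call(rbind, snps)
    n <- nrow(snps)
    snps$maf <- runif(n, maf_range[1], maf_range[2])
    snps$info <- runif(n, 0.92, 1)
    pass <- runif(n) < pass_fraction
    # which of the three conditions carries the pass (may be several)
    which_pass <- matrix(runif(3 * n) < 0.5, ncol = 3)
    none <- pass & rowSums(which_pass) == 0
    which_pass[none, 1] <- TRUE
    snps$cadd <- ifelse(pass & which_pass[, 1], runif(n, 10, 40), runif(n, 0, 9.5))
    snps$gwava <- ifelse(pass & which_pass[, 2], runif(n, 0.5, 1), runif(n, 0, 0.45))
    snps$trap <- ifelse(pass & which_pass[, 3], runif(n, 0.459, 1), runif(n, 0, 0.45))
    structure(list(genes = genes, enhancers = enhancers, snps = snps),
              class = "annotation_fixture")
  })
}

#' @export
print.annotation_fixture <- function(x, ...) {
  cat("Annotation fixture:", nrow(x$genes), "genes (",
      sum(x$genes$role == "druggable"), "druggable ),",
      nrow(x$enhancers), "enhancers,", nrow(x$snps), "SNPs\n")
  invisible(x)
}

#' Simulate biallelic genotype dosages with LD blocks and population structure
#'
#' Dosages are sums of two simulated haplotypes. Within an LD block, each
#' haplotype allele copies the previous SNP's allele with probability
#' `ld_rho` and is otherwise drawn fresh from its allele frequency
#' (haplotype-copy chain), giving tunable pairwise r2 between adjacent SNPs.
#' With `n_subpops > 1`, per-subpopulation allele frequencies are shifted by
#' `+/- subpop_maf_shift/2` in a random per-SNP direction, so the leading
#' principal components of the standardized dosage matrix separate the
#' subpopulations, mimicking genetic ancestry structure.
#'
#' @param n_samples number of samples (>= 2).
#' @param snp_spec an `annotation_fixture` or a data frame with columns
#'   `snp_id`, `chrom`, `pos`, `maf` (MAFs must lie in (0, 0.5]).
#' @param ld_block_size number of consecutive SNPs per LD block (1 = no LD).
#' @param ld_rho haplotype copy probability within a block, in [0, 1).
#' @param n_subpops number of latent subpopulations.
#' @param subpop_maf_shift total allele-frequency shift between extreme
#'   subpopulations.
#' @param seed RNG seed; generation is bit-reproducible given (parameters,
#'   seed).
#' @return a numeric samples x SNPs matrix of dosages in [0, 2] with sample
#'   ids as row names and SNP ids as column names, of class
#'   `genotype_matrix`; the latent subpopulation labels are kept in
#'   `attr(, "subpop")` for validation and are not used by any modelling
#'   stage.
#' @export
simulate_genotypes <- function(n_samples, snp_spec, ld_block_size = 1,
                               ld_rho = 0, n_subpops = 1,
                               subpop_maf_shift = 0.2, seed = 1) {
  if (length(n_samples) != 1L || n_samples < 2)
    stop("n_samples must be a single count >= 2", call. = FALSE)
  snps <- if (inherits(snp_spec, "annotation_fixture")) snp_spec$snps else snp_spec
  stopifnot(is.data.frame(snps), all(c("snp_id", "maf") %in% names(snps)))
  if (any(snps$maf <= 0 | snps$maf > 0.5))
    stop("MAFs must lie in (0, 0.5]", call. = FALSE)
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)", call. = FALSE)
  if (!is.null(snps$chrom) && !is.null(snps$pos))
    snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  m <- nrow(snps)
  n <- as.integer(n_samples)

  with_seed(seed, {
    subpop <- if (n_subpops > 1) sample.int(n_subpops, n, replace = TRUE)
              else rep(1L, n)
    dir <- sample(c(-1, 1), m, replace = TRUE)
    offsets <- if (n_subpops > 1)
      seq(-subpop_maf_shift / 2, subpop_maf_shift / 2, length.out = n_subpops)
    else 0
    # block id: consecutive runs of ld_block_size within a chromosome
    chrom <- if (!is.null(snps$chrom)) snps$chrom else rep("1", m)
    block <- integer(m); b <- 0L; run <- 0L; last_chrom <- ""
    for (j in seq_len(m)) {
      if (chrom[j] != last_chrom || run >= ld_block_size) {
        b <- b + 1L; run <- 0L; last_chrom <- chrom[j]
      }
      block[j] <- b; run <- run + 1L
    }
    G <- matrix(0, n, m)
    for (k in seq_len(n_subpops)) {
      rows <- which(subpop == k)
      if (!length(rows)) next
      p <- pmin(pmax(snps$maf + dir * offsets[k], 0.01), 0.99)
      nk <- length(rows)
      for (hap in 1:2) {
        H <- matrix(0L, nk, m)
        for (j in seq_len(m)) {
          fresh <- rbinom(nk, 1L, p[j])
          if (j > 1L && block[j] == block[j - 1L] && ld_rho > 0) {
            copy <- rbinom(nk, 1L, ld_rho)
            H[, j] <- copy * H[, j - 1L] + (1L - copy) * fresh
          } else H[, j] <- fresh
        }
        G[rows, ] <- G[rows, ] + H
      }
    }
    dimnames(G) <- list(sprintf("S%06d", seq_len(n)), snps$snp_id)
    attr(G, "subpop") <- subpop
    class(G) <- c("genotype_matrix", class(G))
    G
  })
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype dosage matrix:", nrow(x), "samples x", ncol(x), "SNPs\n")
  sp <- attr(x, "subpop")
  if (!is.null(sp) && length(unique(sp)) > 1L)
    cat("  latent subpopulations:", length(unique(sp)), "\n")
  invisible(x)
}

#' Principal components of a standardized dosage matrix
#'
#' Truncated SVD of the column-standardized dosages, mimicking the genetic PCs
#' a biobank supplies as ancestry covariates.
#'
#' @param G genotype dosage matrix.
#' @param k number of components (padded with zero columns if `k` exceeds the
#'   available rank).
#' @return an `n x k` matrix with columns `pc1..pck`.
#' @export
genotype_pcs <- function(G, k = 10) {
  X <- unclass(G)
  attr(X, "subpop") <- NULL
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  keff <- min(k, ncol(Z), nrow(Z) - 1L)
  s <- svd(Z, nu = keff, nv = 0)
  pcs <- s$u %*% diag(s$d[seq_len(keff)], keff, keff)
  if (keff < k) pcs <- cbind(pcs, matrix(0, nrow(Z), k - keff))
  colnames(pcs) <- paste0("pc", seq_len(k))
  rownames(pcs) <- rownames(G)
  pcs
}

#' Define a generative phenotype model with heterogeneous case subgroups
#'
#' Each sample belongs to a latent subgroup; its case probability is
#' `logistic(baseline + sum(beta * dosage) over the subgroup's causal set +
#' covariate terms)`. Different subgroups may carry disjoint causal SNP sets,
#' emulating genetic heterogeneity (different SNPs driving the trait in
#' different subjects).
#'
#' @param subgroup_fractions probabilities over latent subgroups (must sum to
#'   1 within 1e-12).
#' @param causal_sets list (one element per subgroup) of named numeric vectors
#'   of per-SNP log-odds effects; names are SNP ids.
#' @param baseline_log_odds intercept of the liability.
#' @param covariate_effects named list with elements `age` (per year, age
#'   centered at 57), `sex`, `array` and `pcs` (length-10 vector). Defaults:
#'   weak age and sex effects, zero array and PC effects.
#' @param seed RNG seed used by [simulate_phenotype()].
#' @return an object of class `generative_model`.
#' @export
generative_model <- function(subgroup_fractions = 1,
                             causal_sets = list(numeric(0)),
                             baseline_log_odds = 0,
                             covariate_effects = list(),
                             seed = 1) {
  if (abs(sum(subgroup_fractions) - 1) > 1e-12)
    stop("subgroup_fractions must sum to 1", call. = FALSE)
  if (length(causal_sets) != length(subgroup_fractions))
    stop("one causal set per subgroup required", call. = FALSE)
  ce <- list(age = 0.01, sex = 0.1, array = 0, pcs = rep(0, 10))
  ce[names(covariate_effects)] <- covariate_effects
  structure(list(subgroup_fractions = subgroup_fractions,
                 causal_sets = lapply(causal_sets, function(b) {
                   b <- unlist(b)
                   if (length(b) && is.null(names(b)))
                     stop("causal effects must be named by snp_id", call. = FALSE)
                   b
                 }),
                 baseline_log_odds = baseline_log_odds,
                 covariate_effects = ce, seed = seed),
            class = "generative_model")
}

check_causal_snps <- function(model, G) {
  ids <- unique(unlist(lapply(model$causal_sets, names)))
  missing <- setdiff(ids, colnames(G))
  if (length(missing))
    stop("causal SNPs absent from genotype matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# Genetic part of the linear predictor, per subgroup: n x n_subgroups matrix.
genetic_eta <- function(model, G) {
  sapply(seq_along(model$causal_sets), function(g) {
    b <- model$causal_sets[[g]]
    if (!length(b)) return(rep(0, nrow(G)))
    as.numeric(G[, names(b), drop = FALSE] %*% b)
  })
}

#' Simulate a binary endpoint and covariates from a generative model
#'
#' Assigns each sample a latent subgroup, draws covariates (age, sex,
#' genotyping-array indicator) and computes genetic PCs from the dosage
#' matrix, then draws the phenotype from the model's per-sample logistic case
#' probability.
#'
#' @param G genotype dosage matrix.
#' @param model a [generative_model()].
#' @return a `data.frame` cohort table with columns `sample_id`, `phenotype`
#'   (1 = case), `age`, `sex`, `pc1..pc10`, `array`. The latent subgroup
#'   labels and true case probabilities are attached as attributes `subgroup`
#'   and `case_prob` for validation only.
#' @export
simulate_phenotype <- function(G, model) {
  stopifnot(inherits(model, "generative_model"))
  assert_dosage_matrix(unclass(G))
  check_causal_snps(model, G)
  n <- nrow(G)
  pcs <- genotype_pcs(G, 10)
  with_seed(model$seed, {
    subgroup <- sample.int(length(model$subgroup_fractions), n, replace = TRUE,
                           prob = model$subgroup_fractions)
    age <- round(rnorm(n, 57, 8))
    sex <- rbinom(n, 1, 0.5)
    array <- rbinom(n, 1, 0.95)
    ce <- model$covariate_effects
    eta_g <- genetic_eta(model, G)
    eta <- model$baseline_log_odds +
      eta_g[cbind(seq_len(n), subgroup)] +
      ce$age * (age - 57) + ce$sex * sex + ce$array * array +
      as.numeric(pcs %*% ce$pcs)
    p <- stats::plogis(eta)
    phenotype <- rbinom(n, 1, p)
    out <- data.frame(sample_id = rownames(G), phenotype = phenotype,
                      age = age, sex = sex, pcs, array = array,
                      stringsAsFactors = FALSE)
    attr(out, "subgroup") <- subgroup
    attr(out, "case_prob") <- p
    out
  })
}

#' Genotype-only Bayes accuracy of a generative model
#'
#' Expected accuracy of the Bayes-optimal classifier that observes the
#' genotypes (marginalising over the latent subgroup, covariate terms
#' excluded): the average over samples of `max(p, 1 - p)` where `p` is the
#' marginal case probability given the dosages.
#'
#' @inheritParams simulate_phenotype
#' @return a number in [0.5, 1] (up to Monte-Carlo variation in `G`).
#' @export
bayes_accuracy <- function(model, G) {
  stopifnot(inherits(model, "generative_model"))
  check_causal_snps(model, G)
  eta_g <- genetic_eta(model, G)
  p <- as.numeric(stats::plogis(model$baseline_log_odds + eta_g) %*%
                    model$subgroup_fractions)
  mean(pmax(p, 1 - p))
}
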