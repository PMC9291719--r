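# Biologically grouped SNP feature sets: promoter-extended gene intervals,
# SNP-to-gene mapping (body vs enhancer), QC and functionality-score filters,
# greedy LD pruning, and assembly of one feature set per
# (druggable gene, connected gene) pair.
#
# All coordinates are BED-style 0-based half-open; a SNP at position p is the
# interval [p, p+1), so a SNP at the exact end coordinate of an interval lies
# outside it.

#' Extend gene intervals by a promoter window around the TSS
#'
#' Each gene's interval becomes the union of its body and the window
#' `[TSS - upstream, TSS + downstream)` in strand-oriented coordinates: the
#' TSS is `start` for `+` genes and `end` for `-` genes, and the upstream
#' direction is reversed on the `-` strand. Extended starts are clipped at 0.
#'
#' @param genes data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`+`/`-`).
#' @param upstream,downstream promoter window in bases (defaults 5000 / 1000).
#' @param strand_aware if `FALSE`, all genes are treated as `+` strand
#'   (strand-agnostic extension).
#' @return the input data frame with `start`/`end` replaced by the extended
#'   interval.
#' @export
extend_gene_intervals <- function(genes, upstream = 5000, downstream = 1000,
                                  strand_aware = TRUE) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  if (any(genes$start >= genes$end))
    stop("gene intervals must satisfy start < end", call. = FALSE)
  strand <- if (strand_aware) genes$strand else rep("+", nrow(genes))
  bad <- !strand %in% c("+", "-")
  if (any(bad))
    stop("unknown strand for gene(s): ",
         paste(genes$gene_id[bad], collapse = ", "), call. = FALSE)
  plus <- strand == "+"
  new_start <- ifelse(plus, pmin(genes$start, genes$start - upstream),
                      pmin(genes$start, genes$end - downstream))
  new_end <- ifelse(plus, pmax(genes$end, genes$start + downstream),
                    pmax(genes$end, genes$end + upstream))
  out <- genes
  out$start <- pmax(0, as.integer(new_start))
  out$end <- as.integer(new_end)
  out
}

# Fail loudly when 'chr1' and '1' style chromosome names are mixed.
check_chrom_style <- function(...) {
  chroms <- unlist(list(...), use.names = FALSE)
  chroms <- unique(as.character(chroms))
  pref <- grepl("^chr", chroms)
  if (any(pref) && !all(pref))
    stop("mixed chromosome naming styles ('chr1' vs '1'); ",
         "harmonize inputs before mapping", call. = FALSE)
  invisible(TRUE)
}

#' Map SNPs to one gene's extended body or enhancers
#'
#' A SNP is labeled `B` if its position falls in the (promoter-extended) gene
#' interval, else `E` if it falls in any enhancer interval assigned to that
#' gene; a SNP in both is labeled `B`. SNPs in neither are excluded.
#'
#' @param snps data frame with `snp_id`, `chrom`, `pos`.
#' @param gene_interval one-row data frame (or list) with `chrom`, `start`,
#'   `end` — typically a row of [extend_gene_intervals()] output.
#' @param enhancers data frame of enhancer intervals for this gene
#'   (`chrom`, `start`, `end`), or `NULL`.
#' @return data frame `snp_id`, `region` (`B`/`E`) for the mapped SNPs.
#' @export
map_snps_to_gene <- function(snps, gene_interval, enhancers = NULL) {
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snps)))
  check_chrom_style(snps$chrom, gene_interval$chrom,
                    if (!is.null(enhancers)) enhancers$chrom)
  in_body <- snps$chrom == gene_interval$chrom &
    snps$pos >= gene_interval$start & snps$pos < gene_interval$end
  in_enh <- rep(FALSE, nrow(snps))
  if (!is.null(enhancers) && nrow(enhancers)) {
    for (i in seq_len(nrow(enhancers))) {
      in_enh <- in_enh | (snps$chrom == enhancers$chrom[i] &
                            snps$pos >= enhancers$start[i] &
                            snps$pos < enhancers$end[i])
    }
  }
  keep <- in_body | in_enh
  data.frame(snp_id = snps$snp_id[keep],
             region = ifelse(in_body[keep], "B", "E"),
             stringsAsFactors = FALSE)
}

#' Filter SNPs on MAF and imputation quality
#'
#' Retains SNPs with `maf > maf_min` and `info > info_min` (both strict
#' inequalities, so a SNP exactly at a threshold is excluded).
#'
#' @param snps data frame with at least `snp_id`, `maf`, `info`.
#' @param maf_min,info_min thresholds (defaults 0.01 and 0.9).
#' @return the retained rows of `snps`.
#' @export
filter_snps_qc <- function(snps, maf_min = 0.01, info_min = 0.9) {
  stopifnot(all(c("maf", "info") %in% names(snps)))
  bad <- is.na(snps$maf) | is.na(snps$info)
  if (any(bad))
    stop("missing maf/info for SNP(s): ",
         paste(snps$snp_id[bad], collapse = ", "), call. = FALSE)
  snps[snps$maf > maf_min & snps$info > info_min, , drop = FALSE]
}

#' Filter SNPs on functionality scores
#'
#' Retains SNPs satisfying at least one of: CADD scaled score `>= cadd_min`,
#' GWAVA score `>= gwava_min`, TraP score `>= trap_min` (all inclusive).
#' A missing score fails its condition; a SNP with all three scores missing is
#' rejected with an error.
#'
#' @param snps data frame with `snp_id`, `cadd`, `gwava`, `trap`.
#' @param cadd_min,gwava_min,trap_min thresholds (defaults 10, 0.5, 0.459).
#' @return the retained rows of `snps`.
#' @export
filter_snps_by_scores <- function(snps, cadd_min = 10, gwava_min = 0.5,
                                  trap_min = 0.459) {
  stopifnot(all(c("cadd", "gwava", "trap") %in% names(snps)))
  all_missing <- is.na(snps$cadd) & is.na(snps$gwava) & is.na(snps$trap)
  if (any(all_missing))
    stop("all functionality scores missing for SNP(s): ",
         paste(snps$snp_id[all_missing], collapse = ", "), call. = FALSE)
  ge <- function(x, thr) !is.na(x) & x >= thr
  keep <- ge(snps$cadd, cadd_min) | ge(snps$gwava, gwava_min) |
    ge(snps$trap, trap_min)
  snps[keep, , drop = FALSE]
}

#' Greedy LD pruning of SNPs by squared dosage correlation
#'
#' Scans SNPs in the given order (default: the column order of `G`, i.e.
#' genomic position for matrices from [simulate_genotypes()]); a SNP is
#' retained iff its squared Pearson correlation with every already-retained
#' SNP is `<= r2_max`. Deterministic given the order. Zero-variance columns
#' are treated as uncorrelated, retained, and flagged in the result's
#' `"flagged"` attribute.
#'
#' @param G genotype dosage matrix containing all SNPs in `snp_order`.
#' @param snp_order character vector of SNP ids defining the scan order.
#' @param r2_max retention threshold on r^2 (0.8 in the main analysis; 0.6 for
#'   the GWAS-loci baseline — a parameter, not a second code path).
#' @return character vector of retained SNP ids, in scan order.
#' @export
ld_prune <- function(G, snp_order = colnames(G), r2_max = 0.8) {
  assert_dosage_matrix(unclass(G))
  missing <- setdiff(snp_order, colnames(G))
  if (length(missing))
    stop("SNPs absent from genotype matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  retained <- character(0)
  flagged <- character(0)
  vars <- apply(G[, snp_order, drop = FALSE], 2, stats::var)
  for (s in snp_order) {
    if (vars[[s]] == 0) {
      flagged <- c(flagged, s)
      retained <- c(retained, s)
      next
    }
    ok <- TRUE
    if (length(retained)) {
      r <- suppressWarnings(stats::cor(G[, s], G[, retained, drop = FALSE]))
      r[is.na(r)] <- 0  # against zero-variance retained columns
      ok <- all(r^2 <= r2_max)
    }
    if (ok) retained <- c(retained, s)
  }
  if (length(flagged))
    warning("zero-variance SNP(s) retained as uncorrelated: ",
            paste(flagged, collapse = ", "), call. = FALSE)
  attr(retained, "flagged") <- flagged
  retained
}

#' Assemble feature sets from a SNP-gene map
#'
#' One feature set (FS) per (druggable gene, connected gene) pair, named
#' `"<druggable>:<connected>"`, containing the union of the retained SNPs of
#' both genes, deduplicated and ordered by genomic position (when `snps` is
#' supplied) or by SNP id. By construction any two FSs of the same druggable
#' gene share all of that gene's SNPs.
#'
#' @param snp_gene_map data frame `gene_id`, `snp_id`, `region` — the
#'   concatenated per-gene outputs of [map_snps_to_gene()], restricted to SNPs
#'   surviving the filters and LD pruning.
#' @param genes gene table with `gene_id`, `role`, `druggable_parent`.
#' @param snps optional SNP table with `snp_id`, `chrom`, `pos` used to order
#'   FS members by position.
#' @return an object of class `fs_map`: a named list of character vectors of
#'   SNP ids, with a `meta` attribute linking each FS to its gene pair.
#' @export
build_feature_sets <- function(snp_gene_map, genes, snps = NULL) {
  stopifnot(all(c("gene_id", "snp_id") %in% names(snp_gene_map)))
  connected <- genes[genes$role == "connected", , drop = FALSE]
  if (any(is.na(connected$druggable_parent)))
    stop("connected gene without druggable_parent: ",
         paste(connected$gene_id[is.na(connected$druggable_parent)],
               collapse = ", "), call. = FALSE)
  snps_of <- function(g) unique(snp_gene_map$snp_id[snp_gene_map$gene_id == g])
  order_snps <- function(ids) {
    if (!is.null(snps)) {
      idx <- match(ids, snps$snp_id)
      ids[order(snps$chrom[idx], snps$pos[idx])]
    } else sort(ids)
  }
  fs <- list()
  meta <- list()
  for (i in seq_len(nrow(connected))) {
    cg <- connected$gene_id[i]
    dg <- connected$druggable_parent[i]
    members <- order_snps(union(snps_of(dg), snps_of(cg)))
    name <- paste0(dg, ":", cg)
    fs[[name]] <- members
    meta[[name]] <- data.frame(fs = name, druggable = dg, connected = cg,
                               size = length(members), stringsAsFactors = FALSE)
  }
  structure(fs, meta = do.call(rbind, meta), class = "fs_map")
}

#' @export
print.fs_map <- function(x, ...) {
  sizes <- lengths(x)
  cat("Feature-set map:", length(x), "feature sets; sizes",
      if (length(x)) paste0(min(sizes), "-", max(sizes)) else "-", "\n")
  invisible(x)
}

#' Write / read a feature-set definition file
#'
#' Tab-delimited, one row per feature set: `name`, `size`, comma-separated
#' `snps`. `read_fs_file(write_fs_file(x, path))` reproduces `x`.
#'
#' @param fs_map an `fs_map`.
#' @param path file path.
#' @return `write_fs_file` returns `path` invisibly; `read_fs_file` returns an
#'   `fs_map`.
#' @export
write_fs_file <- function(fs_map, path) {
  if (anyDuplicated(names(fs_map)))
    stop("duplicate feature-set names", call. = FALSE)
  df <- data.frame(name = names(fs_map), size = unname(lengths(fs_map)),
                   snps = vapply(fs_map, paste, "", collapse = ","),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fs_file
#' @export
read_fs_file <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  fs <- lapply(df$snps, function(s) if (nzchar(s)) strsplit(s, ",")[[1]] else character(0))
  names(fs) <- df$name
  bad <- lengths(fs) != as.integer(df$size)
  if (any(bad))
    stop("size field disagrees with SNP list for: ",
         paste(df$name[bad], collapse = ", "), call. = FALSE)
  structure(fs, class = "fs_map")
}

# Plain-text interval / score-table I/O ---------------------------------------

#' Read and write BED-like interval files
#'
#' Minimal tab-delimited interval I/O (0-based half-open, no header for plain
#' BED). Extra columns beyond chrom/start/end/name are preserved, so the
#' gene files can carry `strand`, `role` and `druggable_parent` and enhancer
#' files `tissue`.
#'
#' @param df data frame with at least `chrom`, `start`, `end`.
#' @param path file path.
#' @param col_names column order to write (first three must be chrom, start,
#'   end).
#' @return `read_bed` returns a data frame; `write_bed` returns `path`
#'   invisibly.
#' @export
write_bed <- function(df, path, col_names = names(df)) {
  stopifnot(all(c("chrom", "start", "end") %in% col_names))
  utils::write.table(df[, col_names, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$chrom <- as.character(df$chrom)
  df
}

#' Read and write the per-SNP score table
#'
#' Tab-delimited with columns `snp_id`, `chrom`, `pos`, `maf`, `info`,
#' `cadd`, `gwava`, `trap`.
#'
#' @param snps SNP score data frame.
#' @param path file path.
#' @export
write_snp_table <- function(snps, path) {
  cols <- c("snp_id", "chrom", "pos", "maf", "info", "cadd", "gwava", "trap")
  stopifnot(all(cols %in% names(snps)))
  utils::write.table(snps[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_table
#' @export
read_snp_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$chrom <- as.character(df$chrom)
  df
}

#' Build the full feature-set map from annotation inputs
#'
#' Convenience wrapper chaining the construction steps: promoter extension,
#' SNP-to-gene mapping (body/enhancer), MAF/info QC, functionality-score
#' filtering, per-druggable-gene LD pruning, and FS assembly.
#'
#' @param annotation an `annotation_fixture` (or list with `genes`,
#'   `enhancers`, `snps`).
#' @param G genotype dosage matrix (used for LD pruning).
#' @param r2_max LD pruning threshold.
#' @param upstream,downstream promoter window.
#' @param maf_min,info_min QC thresholds.
#' @return an `fs_map`.
#' @export
build_fs_from_annotation <- function(annotation, G, r2_max = 0.8,
                                     upstream = 5000, downstream = 1000,
                                     maf_min = 0.01, info_min = 0.9) {
  genes <- annotation$genes
  ext <- extend_gene_intervals(genes, upstream, downstream)
  snps <- filter_snps_by_scores(filter_snps_qc(annotation$snps,
                                               maf_min, info_min))
  maps <- lapply(seq_len(nrow(ext)), function(i) {
    enh <- annotation$enhancers[annotation$enhancers$gene_id == ext$gene_id[i], ,
                                drop = FALSE]
    m <- map_snps_to_gene(snps, ext[i, ], enh)
    if (nrow(m)) cbind(gene_id = ext$gene_id[i], m) else NULL
  })
  snp_gene_map <- do.call(rbind, maps)
  # prune within each druggable gene's SNP universe (gene + connected genes)
  kept <- character(0)
  for (dg in genes$gene_id[genes$role == "druggable"]) {
    fam <- c(dg, genes$gene_id[!is.na(genes$druggable_parent) &
                                 genes$druggable_parent == dg])
    ids <- unique(snp_gene_map$snp_id[snp_gene_map$gene_id %in% fam])
    ids <- ids[ids %in% colnames(G)]
    idx <- match(ids, snps$snp_id)
    ids <- ids[order(snps$chrom[idx], snps$pos[idx])]
    if (length(ids))
      kept <- union(kept, suppressWarnings(ld_prune(G, ids, r2_max)))
  }
  snp_gene_map <- snp_gene_map[snp_gene_map$snp_id %in% kept, , drop = FALSE]
  build_feature_sets(snp_gene_map, genes, snps = annotation$snps)
}
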