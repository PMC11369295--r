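#' Write genotypes as a VCF v4.2 text file
#'
#' Emits a minimal VCF with a GT FORMAT field, 1-based positions and
#' unphased diploid genotypes (0/0, 0/1, 1/1); missing genotypes are
#' written as `./.`.
#'
#' @param genotypes SNVs x samples matrix with entries 0/1/2 or NA.
#' @param snv_meta data.frame with `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`, aligned to the rows of `genotypes`.
#' @param path output file.
#' @export
write_vcf <- function(genotypes, snv_meta, path) {
  stopifnot(nrow(genotypes) == nrow(snv_meta))
  gt <- matrix(c("0/0", "0/1", "1/1")[as.matrix(genotypes) + 1L],
               nrow = nrow(genotypes))
  gt[is.na(gt)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(genotypes)), collapse = "\t"))
  body <- cbind(paste0("chr", snv_meta$chrom), snv_meta$pos,
                snv_meta$variant_id, snv_meta$ref, snv_meta$alt,
                ".", "PASS", ".", "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a VCF into an additive genotype matrix
#'
#' Parses with `vcfR`; `0/0`, `0/1`, `1/1` (or phased `|`) map to 0, 1, 2
#' and `./.` to NA.
#'
#' @param path VCF file.
#' @return list with `genotypes` (SNVs x samples) and `snv_meta`.
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  num <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  num[clean == "0/0"] <- 0
  num[clean %in% c("0/1", "1/0")] <- 1
  num[clean == "1/1"] <- 2
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  meta <- data.frame(variant_id = fix$ID,
                     chrom = as.integer(sub("^chr", "", fix$CHROM)),
                     pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT)
  rownames(num) <- meta$variant_id
  list(genotypes = num, snv_meta = meta)
}

write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a synthetic cohort and its companion fixtures to disk
#'
#' Produces the flat-file layout the pipeline consumes: a VCF v4.2 with
#' the genotypes, TSVs for expression counts, phenotypes + covariates and
#' gene metadata, a GTEx-layout eQTL table, a gene-to-GO-term table with
#' its ancestor closure, and known-gene symbol lists.
#'
#' @param cohort an `adipo_cohort`.
#' @param dir output directory (created if missing).
#' @param annotations optional [simulate_annotations()] output.
#' @param known_genes optional named list of gene-symbol vectors.
#' @return invisibly, the named vector of written paths.
#' @export
write_fixtures <- function(cohort, dir, annotations = NULL, known_genes = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    expression = file.path(dir, "expression.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    genes = file.path(dir, "gene_meta.tsv"))
  write_vcf(cohort$genotypes, cohort$snv_meta, paths["vcf"])
  write_matrix_tsv(cohort$expression, paths["expression"])
  ph <- cbind(sample_id = cohort$sample_ids, cohort$phenotypes,
              cohort$covariates)
  write.table(ph, paths["phenotypes"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$gene_meta, paths["genes"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(cohort$eqtl)) {
    paths["eqtl"] <- file.path(dir, "eqtl.tsv")
    write.table(cohort$eqtl, paths["eqtl"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(annotations)) {
    paths["gene2go"] <- file.path(dir, "gene2go.tsv")
    paths["ancestors"] <- file.path(dir, "go_ancestors.tsv")
    paths["term_names"] <- file.path(dir, "go_names.tsv")
    write.table(annotations$gene2term, paths["gene2go"], sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(annotations$ancestors, paths["ancestors"], sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(annotations$term_names, paths["term_names"], sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(known_genes)) {
    for (nm in names(known_genes)) {
      key <- paste0("known_", nm)
      paths[key] <- file.path(dir, paste0("known_", nm, ".tsv"))
      write.table(data.frame(symbol = known_genes[[nm]]), paths[key],
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(paths)
}

#' Read a cohort back from a fixture directory
#'
#' Inverse of [write_fixtures()]: reconstructs genotype, expression and
#' phenotype/covariate tables (matrices round-trip exactly).
#'
#' @param dir directory written by [write_fixtures()].
#' @return an `adipo_cohort` (without generative internals).
#' @export
read_cohort <- function(dir) {
  geno <- read_vcf_genotypes(file.path(dir, "genotypes.vcf"))
  expr <- read_matrix_tsv(file.path(dir, "expression.tsv"))
  ph <- read.delim(file.path(dir, "phenotypes.tsv"))
  gene_meta <- read.delim(file.path(dir, "gene_meta.tsv"))
  covars <- data.frame(
    sex = factor(ph$sex, levels = c("woman", "man")),
    age = ph$age,
    smoking = factor(ph$smoking, levels = c("never", "former", "current")),
    physical_activity = factor(ph$physical_activity,
      levels = c("inactive", "mod_inactive", "mod_active", "active")),
    education = factor(ph$education,
      levels = c("vocational", "technical_college", "university")))
  phen <- ph[, intersect(c("SAT", "TAT", "aSAT", "VAT"), names(ph)),
             drop = FALSE]
  eqtl_path <- file.path(dir, "eqtl.tsv")
  structure(list(
    sample_ids = ph$sample_id,
    expression = expr,
    genotypes = geno$genotypes,
    snv_meta = geno$snv_meta,
    gene_meta = gene_meta,
    phenotypes = phen,
    covariates = covars,
    eqtl = if (file.exists(eqtl_path)) read.delim(eqtl_path) else NULL),
    class = "adipo_cohort")
}

#' Read annotation fixture files
#'
#' @param gene2go_path two-column TSV (`gene_id`, `term_id`).
#' @param ancestors_path two-column TSV (`term_id`, `ancestor_id`).
#' @param names_path optional TSV (`term_id`, `name`).
#' @return an [annotation_set()].
#' @export
read_annotations <- function(gene2go_path, ancestors_path, names_path = NULL) {
  annotation_set(read.delim(gene2go_path), read.delim(ancestors_path),
                 if (!is.null(names_path) && file.exists(names_path))
                   read.delim(names_path) else NULL)
}
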