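#' Gene-set annotation container for GO-style enrichment
#'
#' Bundles a gene-to-term mapping with the transitive term-to-ancestor
#' closure of the ontology. The ancestor relation must be acyclic; roots
#' are terms that appear as ancestors but have none themselves, and
#' "highest-level parents" are the terms directly below a root.
#'
#' @param gene2term data.frame with columns `gene_id`, `term_id`.
#' @param ancestors data.frame with columns `term_id`, `ancestor_id`
#'   (transitive closure, excluding the term itself).
#' @param term_names optional data.frame with `term_id`, `name`.
#' @return an `annotation_set` list with lookup tables.
#' @export
annotation_set <- function(gene2term, ancestors, term_names = NULL) {
  stopifnot(all(c("gene_id", "term_id") %in% names(gene2term)),
            all(c("term_id", "ancestor_id") %in% names(ancestors)))
  anc <- split(ancestors$ancestor_id, ancestors$term_id)
  # cycle check: a term may never be its own (transitive) ancestor
  self <- intersect(ancestors$term_id[ancestors$term_id == ancestors$ancestor_id],
                    names(anc))
  if (length(self)) stop("ancestor relation is cyclic at: ",
                         paste(self, collapse = ", "))
  all_anc <- unique(ancestors$ancestor_id)
  roots <- setdiff(all_anc, ancestors$term_id)
  # a root child's (transitive) ancestors are all roots
  root_children <- names(anc)[vapply(anc, function(a) all(a %in% roots), TRUE)]
  structure(list(
    gene2term = split(gene2term$term_id, gene2term$gene_id),
    term2gene = split(gene2term$gene_id, gene2term$term_id),
    ancestors = anc,
    roots = roots,
    root_children = root_children,
    term_names = term_names), class = "annotation_set")
}

#' GO-term over/under-representation by Fisher's exact test
#'
#' For every term annotated to at least `min_term_size` background genes,
#' builds the 2x2 table (study genes in/out of term vs remaining background
#' genes in/out of term) and computes the two-sided Fisher exact p-value;
#' direction is "over" when the study fraction exceeds the background
#' fraction, "under" when below, "none" at a tie.
#'
#' @param study character vector of study gene ids (must be a subset of
#'   `background`).
#' @param background character vector of analyzed gene ids.
#' @param ann an [annotation_set()].
#' @param min_term_size minimum background annotation count for a term to
#'   be analyzed (default 5).
#' @return data.frame with `term_id`, counts `a`,`b`,`c`,`d`, `direction`,
#'   `p`; attribute `n_analyzed_terms`.
#' @export
fisher_enrichment <- function(study, background, ann, min_term_size = 5) {
  study <- unique(study)
  background <- unique(background)
  bad <- setdiff(study, background)
  if (length(bad))
    stop("study genes missing from background: ", paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else "")
  N <- length(background)
  n_study <- length(study)
  term_bg <- lapply(ann$term2gene, function(g) intersect(g, background))
  sizes <- lengths(term_bg)
  terms <- names(term_bg)[sizes >= min_term_size]
  rows <- lapply(terms, function(tm) {
    in_term <- term_bg[[tm]]
    a <- length(intersect(study, in_term))
    b <- n_study - a
    cc <- length(in_term) - a
    d <- N - a - b - cc
    p <- fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
    dir <- if (a / n_study > length(in_term) / N) "over"
           else if (a / n_study < length(in_term) / N) "under" else "none"
    data.frame(term_id = tm, a = a, b = b, c = cc, d = d,
               direction = dir, p = p)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term_id = character(), a = integer(), b = integer(),
               c = integer(), d = integer(), direction = character(),
               p = numeric())
  attr(out, "n_analyzed_terms") <- length(terms)
  out
}

#' Flag significant terms after multiple-testing correction
#'
#' Bonferroni by default (significant iff `p < alpha / T` with `T` the
#' number of analyzed terms); Holm and Benjamini-Hochberg available.
#'
#' @param rows output of [fisher_enrichment()].
#' @param alpha family-wise (or FDR) level, default 0.05.
#' @param method one of `"bonferroni"`, `"holm"`, `"BH"`.
#' @return `rows` with a `significant` column; attribute `cutoff` for the
#'   Bonferroni case.
#' @export
correct_terms <- function(rows, alpha = 0.05, method = c("bonferroni", "holm", "BH")) {
  method <- match.arg(method)
  if (nrow(rows) == 0) stop("no analyzed terms to correct")
  TT <- attr(rows, "n_analyzed_terms") %||% nrow(rows)
  if (method == "bonferroni") {
    cutoff <- alpha / TT
    rows$significant <- rows$p < cutoff
    attr(rows, "cutoff") <- cutoff
  } else {
    rows$significant <- p.adjust(rows$p, method = method, n = TT) < alpha
  }
  attr(rows, "n_analyzed_terms") <- TT
  rows
}

#' Tally significant terms by highest-level parent
#'
#' Maps each significant term to its ancestor(s) directly below the
#' ontology root (terms that are themselves root children count under
#' themselves) and tallies terms per parent; a term reaching several
#' root-level parents contributes to each. Terms with no route to a root
#' child are counted under `"unmapped"` with a warning.
#'
#' @param sig_terms character vector of significant term ids.
#' @param ann an [annotation_set()].
#' @return data.frame `parent`, `n_terms`, sorted by decreasing tally.
#' @export
summarize_parents <- function(sig_terms, ann) {
  if (length(sig_terms) == 0)
    return(data.frame(parent = character(), n_terms = integer()))
  hits <- lapply(sig_terms, function(tm) {
    if (tm %in% ann$root_children) return(tm)
    par <- intersect(ann$ancestors[[tm]], ann$root_children)
    if (length(par) == 0) {
      warning("term ", tm, " reaches no root-level parent; counted as unmapped")
      return("unmapped")
    }
    par
  })
  tab <- sort(table(unlist(hits)), decreasing = TRUE)
  out <- data.frame(parent = names(tab), n_terms = as.integer(tab),
                    row.names = NULL)
  if (!is.null(ann$term_names)) {
    m <- match(out$parent, ann$term_names$term_id)
    out$name <- ann$term_names$name[m]
  }
  out
}

#' Generate a small GO-style annotation fixture
#'
#' Builds a two-level ontology: one root, a handful of root-level parents
#' named after broad biological processes, and leaf terms each annotated
#' under one or two parents; genes get random leaf annotations. Intended
#' for testing and synthetic pipelines.
#'
#' @param gene_ids character vector of genes to annotate.
#' @param n_terms number of leaf terms.
#' @param terms_per_gene mean annotations per gene.
#' @param seed integer seed.
#' @return list with `gene2term`, `ancestors`, `term_names` data.frames
#'   (the layout [annotation_set()] accepts).
#' @export
simulate_annotations <- function(gene_ids, n_terms = 40, terms_per_gene = 3,
                                 seed = 1) {
  set.seed(seed)
  parents <- c("GO:P01" = "metabolic process", "GO:P02" = "cellular process",
               "GO:P03" = "immune system process", "GO:P04" = "localization",
               "GO:P05" = "biological regulation",
               "GO:P06" = "response to stimulus")
  leaves <- sprintf("GO:L%03d", seq_len(n_terms))
  anc <- lapply(leaves, function(l) {
    k <- sample(1:2, 1, prob = c(0.8, 0.2))
    sample(names(parents), k)
  })
  ancestors <- rbind(
    data.frame(term_id = rep(leaves, lengths(anc)),
               ancestor_id = unlist(anc)),
    data.frame(term_id = rep(leaves, lengths(anc)),
               ancestor_id = "GO:ROOT"),
    data.frame(term_id = names(parents), ancestor_id = "GO:ROOT"))
  ancestors <- unique(ancestors)
  n_ann <- pmax(1, rpois(length(gene_ids), terms_per_gene))
  gene2term <- data.frame(
    gene_id = rep(gene_ids, n_ann),
    term_id = unlist(lapply(n_ann, function(k) sample(leaves, k))))
  term_names <- data.frame(
    term_id = c("GO:ROOT", names(parents), leaves),
    name = c("biological_process", unname(parents),
             sprintf("leaf process %03d", seq_len(n_terms))))
  list(gene2term = gene2term, ancestors = ancestors, term_names = term_names)
}
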