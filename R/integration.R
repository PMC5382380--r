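#' Percentage bookkeeping for DMP/DMR overlaps
#'
#' @param n_overlap,n_total Overlapping and total counts.
#' @return `100 * n_overlap / n_total`, rounded to one decimal.
#' @export
#' @examples
#' overlap_percentage(547, 767) # 71.3
overlap_percentage <- function(n_overlap, n_total) {
  if (n_overlap > n_total) stop("overlap count cannot exceed the total")
  round(100 * n_overlap / n_total, 1)
}

#' Overlap significant DMPs with significant DMRs
#'
#' A DMP overlaps when its position lies within `[start, end]` (inclusive)
#' of any significant DMR on the same chromosome. The unique non-empty
#' gene symbols of the overlapping DMPs (multi-gene annotations split on
#' `;`) form the high-confidence gene list.
#'
#' @param dmps A `dmp_scan` (model-A significant rows are used) or a data
#'   frame with `probe_id`, `chromosome`, `position` and optionally `gene`.
#' @param dmrs A `dmr_scan` or a data frame with `chromosome`, `start`,
#'   `end`.
#' @param model Which DMP model's significant set to use when `dmps` is a
#'   scan object (`"A"` or `"B"`).
#' @return Object of class `overlap_result`: `overlap_ids`, `n_overlap`,
#'   `n_dmps`, `percentage` (one decimal), `genes`.
#' @export
overlap_dmps_dmrs <- function(dmps, dmrs, model = c("A", "B")) {
  model <- match.arg(model)
  if (inherits(dmps, "dmp_scan")) {
    col <- if (model == "A") "sig_model_A" else "sig_model_B"
    dmps <- dmps$table[dmps$table[[col]], , drop = FALSE]
  }
  regions <- if (inherits(dmrs, "dmr_scan")) dmrs$regions else dmrs
  n_dmps <- nrow(dmps)
  hit <- logical(n_dmps)
  if (n_dmps > 0 && nrow(regions) > 0) {
    for (ch in unique(dmps$chromosome)) {
      di <- which(dmps$chromosome == ch)
      rg <- regions[regions$chromosome == ch, , drop = FALSE]
      if (nrow(rg) == 0) next
      for (i in di) {
        hit[i] <- any(dmps$position[i] >= rg$start &
                        dmps$position[i] <= rg$end)
      }
    }
  }
  genes <- if ("gene" %in% names(dmps)) {
    setdiff(unique(unlist(strsplit(dmps$gene[hit], ";"))), c("", NA))
  } else character(0)
  structure(list(overlap_ids = dmps$probe_id[hit],
                 n_overlap = sum(hit), n_dmps = n_dmps,
                 percentage = if (n_dmps > 0) {
                   overlap_percentage(sum(hit), n_dmps)
                 } else NA_real_,
                 genes = sort(genes)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap_result: %d of %d sig-DMPs (%.1f%%) inside a sig-DMR; %d high-confidence genes\n",
              x$n_overlap, x$n_dmps, x$percentage, length(x$genes)))
  invisible(x)
}

# One Fisher row. The 2x2 table is DMP vs non-DMP background (rows must be
# disjoint), in-category vs out-of-category; a + b = number of DMPs.
.fisher_row <- function(category, a, b, c_, d) {
  flag <- ""
  or <- (a * d) / (b * c_)
  if (!is.finite(or)) {
    or <- if (a == 0 || d == 0) 0 else Inf
    flag <- "zero_cell"
  }
  if (a == 0) {
    or <- 0
    flag <- "zero_cell"
  }
  p <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2,
                                 byrow = TRUE))$p.value
  data.frame(category = category, a = a, b = b, c = c_, d = d,
             odds_ratio = or, p = p, flag = flag, stringsAsFactors = FALSE)
}

.finish_enrichment <- function(tab, adjust, alpha = 0.05) {
  tab$p_adjusted <- stats::p.adjust(tab$p, method = adjust)
  tab$adjust_method <- adjust
  tab$call <- ifelse(is.na(tab$p_adjusted) | tab$p_adjusted >= alpha, "ns",
                     ifelse(tab$odds_ratio > 1, "enriched", "depleted"))
  class(tab) <- c("enrichment_result", "data.frame")
  tab
}

#' Fisher-exact enrichment of DMPs over an annotation column
#'
#' For each level of a categorical manifest annotation (gene element, CpG
#' context, chromatin state, ...) a two-sided Fisher exact test compares
#' the significant DMPs against the remaining background probes. The
#' two-sided p sums all tables with probability at most that of the
#' observed one (the classical convention). No multiplicity adjustment is
#' applied by default.
#'
#' @param dmp_ids Probe ids of the significant DMPs.
#' @param background_ids All analysed probe ids (must contain the DMPs).
#' @param manifest Probe manifest with the category `column`.
#' @param column Manifest column name.
#' @param adjust `"none"` (default), `"bonferroni"` or `"BH"`.
#' @return An `enrichment_result` data frame: category, the 2x2 counts
#'   `a, b, c, d`, sample odds ratio, `p`, `p_adjusted`, `call` in
#'   `{enriched, depleted, ns}` (at adjusted p < 0.05), `flag`.
#' @export
annotation_enrichment <- function(dmp_ids, background_ids, manifest, column,
                                  adjust = c("none", "bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  if (!all(dmp_ids %in% background_ids)) {
    stop("background must contain all DMP ids")
  }
  ann <- manifest[[column]][match(background_ids, manifest$probe_id)]
  is_dmp <- background_ids %in% dmp_ids
  levels_bg <- sort(unique(ann[!is.na(ann)]))
  rows <- lapply(levels_bg, function(lv) {
    in_cat <- !is.na(ann) & ann == lv
    .fisher_row(lv,
                a = sum(is_dmp & in_cat), b = sum(is_dmp & !in_cat),
                c_ = sum(!is_dmp & in_cat), d = sum(!is_dmp & !in_cat))
  })
  .finish_enrichment(do.call(rbind, rows), adjust)
}

#' Parse semicolon-joined TFBS annotations into membership sets
#'
#' @param manifest Probe manifest with a `tfbs` column of `;`-joined
#'   labels.
#' @param probe_ids Probes to restrict to (default all).
#' @return Named list mapping each TFBS label to its member probe ids.
#' @export
tfbs_sets_from_manifest <- function(manifest, probe_ids = manifest$probe_id) {
  mf <- manifest[match(probe_ids, manifest$probe_id), , drop = FALSE]
  lab <- strsplit(mf$tfbs, ";")
  reps <- lengths(lab)
  long <- data.frame(probe = rep(mf$probe_id, reps),
                     tf = unlist(lab), stringsAsFactors = FALSE)
  long <- long[long$tf != "", , drop = FALSE]
  split(long$probe, long$tf)
}

#' TFBS enrichment with Bonferroni control
#'
#' Fisher exact test of the significant DMPs against the analysed
#' background for each transcription-factor binding-site set, with
#' Bonferroni adjustment across the number of sets tested; a set is called
#' enriched at adjusted p < 0.05. The universe is the set of probes
#' retained after filtering (the analysed array content), not the full
#' array.
#'
#' @param dmp_ids Significant DMP probe ids.
#' @param background_ids Analysed background probe ids.
#' @param tfbs_sets Named list of probe-id vectors (see
#'   [tfbs_sets_from_manifest()]).
#' @return An `enrichment_result` data frame, one row per TFBS.
#' @export
tfbs_enrichment <- function(dmp_ids, background_ids, tfbs_sets) {
  if (!all(dmp_ids %in% background_ids)) {
    stop("background must contain all DMP ids")
  }
  is_dmp <- background_ids %in% dmp_ids
  rows <- lapply(names(tfbs_sets), function(tf) {
    in_set <- background_ids %in% tfbs_sets[[tf]]
    .fisher_row(tf,
                a = sum(is_dmp & in_set), b = sum(is_dmp & !in_set),
                c_ = sum(!is_dmp & in_set), d = sum(!is_dmp & !in_set))
  })
  .finish_enrichment(do.call(rbind, rows), "bonferroni")
}

#' Gene-set enrichment of the high-confidence gene list
#'
#' Fisher exact test of a gene list against user-supplied gene sets (e.g.
#' a GMT file read with [read_gmt()]) over a stated gene universe, ranked
#' by `-log10(p)`.
#'
#' @param genes Character vector of gene symbols.
#' @param gene_sets Named list of gene-symbol vectors.
#' @param universe Character vector: the gene universe (must be
#'   non-empty; genes outside it are dropped with a message).
#' @return An `enrichment_result` data frame with an extra
#'   `neg_log10_p` column, sorted by decreasing `neg_log10_p`.
#' @export
gene_set_enrichment <- function(genes, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("gene universe is empty")
  dropped <- setdiff(genes, universe)
  if (length(dropped)) {
    message(length(dropped), " gene(s) outside the universe dropped")
  }
  genes <- intersect(unique(genes), universe)
  in_list <- universe %in% genes
  rows <- lapply(names(gene_sets), function(gs) {
    in_set <- universe %in% gene_sets[[gs]]
    .fisher_row(gs,
                a = sum(in_list & in_set), b = sum(in_list & !in_set),
                c_ = sum(!in_list & in_set), d = sum(!in_list & !in_set))
  })
  tab <- .finish_enrichment(do.call(rbind, rows), "none")
  tab$neg_log10_p <- -log10(tab$p)
  tab[order(-tab$neg_log10_p), , drop = FALSE]
}

#' Map genes to disease associations above a reliability score
#'
#' Joins a gene list to a local gene-disease association table, keeping
#' associations with score strictly above `min_score` (default 0.1; a
#' score of exactly 0.1 is excluded).
#'
#' @param genes Character vector of gene symbols.
#' @param association_table Data frame with columns `gene`, `disease`,
#'   `score`.
#' @param min_score Strict lower bound on the score (default 0.1).
#' @return The filtered, joined data frame (possibly zero rows).
#' @export
disease_mapping <- function(genes, association_table, min_score = 0.1) {
  stopifnot(all(c("gene", "disease", "score") %in%
                  names(association_table)))
  out <- association_table[association_table$score > min_score &
                             association_table$gene %in% genes, ,
                           drop = FALSE]
  rownames(out) <- NULL
  out
}
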