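# Avogadro's number and the gram -> femtogram factor used throughout the
# mass-budget model.
AVOGADRO <- 6.02214076e23
FG_PER_G <- 1e15

#' Per-gene translation efficiency from reference proteome and WT transcripts
#'
#' The translation efficiency s_i = copies_wt / r_wt converts a transcript
#' abundance (FPKM) into protein copies per cell, anchored on the reference
#' condition where both are known. Genes with r_wt = 0 have no defined
#' efficiency and are excluded; they are listed in the attached exclusion
#' report rather than silently dropped.
#'
#' @param table a `GeneBudgetTable` (see [read_gene_table()]) or data.frame
#'   with columns `id`, `r_wt`, `r_mut`, `copies_wt`, `mw`.
#' @return the table restricted to genes with r_wt > 0, with an `s_i`
#'   column (copies per cell per FPKM) and attribute `excluded` (character
#'   vector of excluded gene ids).
#' @export
compute_translation_efficiency <- function(table) {
  table <- as.data.frame(table)
  if (!nrow(table)) stop("empty gene table")
  stopifnot(all(c("id", "r_wt", "copies_wt") %in% names(table)))
  excluded <- table$id[table$r_wt == 0]
  out <- table[table$r_wt > 0, , drop = FALSE]
  out$s_i <- out$copies_wt / out$r_wt
  attr(out, "excluded") <- excluded
  out
}

#' Protein mass from transcript abundance under the translation-efficiency model
#'
#' P_i = r * s_i * MW / N_A grams, returned in femtograms. With r equal to
#' the WT transcript abundance this reduces exactly to
#' copies_wt * MW / N_A, the mass of the reference protein pool.
#'
#' @param r transcript abundance (FPKM), vectorized.
#' @param s_i translation efficiency (copies per cell per FPKM).
#' @param mw protein molecular weight (g/mol).
#' @return protein mass per cell in femtograms.
#' @export
estimate_protein_mass <- function(r, s_i, mw) {
  if (any(r < 0) || any(s_i < 0) || any(mw < 0))
    stop("r, s_i and mw must all be non-negative")
  r * s_i * mw / AVOGADRO * FG_PER_G
}

#' Per-gene proteome mass-contribution deltas and direction/category totals
#'
#' Applies the mass model to WT and mutant transcript abundances and takes
#' delta_i = P_mut,i - P_wt,i as gene i's contribution to the proteome
#' change (femtograms per cell). Totals are reported per DE direction and
#' per functional category, both as signed sums and as sums of |delta|; the
#' up/|down| ratio uses the absolute sums of the genes labelled up and down.
#'
#' @param table gene table with `s_i` (from
#'   [compute_translation_efficiency()]).
#' @return list of class `MassContributionSet`: `genes` (data.frame: id,
#'   s_i, p_wt, p_mut, delta, direction, category, rank, cumulative_frac),
#'   `by_direction` and `by_category` (signed and absolute totals),
#'   `up_total`, `down_total` (sums of |delta| over up/down genes),
#'   `ratio_up_down`, `excluded`.
#' @export
mass_contribution_deltas <- function(table) {
  table <- as.data.frame(table)
  if (!"s_i" %in% names(table))
    stop("run compute_translation_efficiency() first")
  if (!"direction" %in% names(table)) table$direction <- "unchanged"
  if (!"category" %in% names(table)) table$category <- "other"
  p_wt <- estimate_protein_mass(table$r_wt, table$s_i, table$mw)
  p_mut <- estimate_protein_mass(table$r_mut, table$s_i, table$mw)
  genes <- data.frame(id = table$id, s_i = table$s_i,
                      p_wt = p_wt, p_mut = p_mut, delta = p_mut - p_wt,
                      direction = table$direction, category = table$category,
                      stringsAsFactors = FALSE)
  # ranking by |delta| descending, ties broken lexicographically by id
  ord <- order(-abs(genes$delta), genes$id)
  genes <- genes[ord, , drop = FALSE]
  genes$rank <- seq_len(nrow(genes))
  tot <- sum(abs(genes$delta))
  genes$cumulative_frac <- if (tot > 0) cumsum(abs(genes$delta)) / tot else
    rep(1, nrow(genes))
  rownames(genes) <- NULL
  agg <- function(key) {
    signed <- tapply(genes$delta, genes[[key]], sum)
    absolute <- tapply(abs(genes$delta), genes[[key]], sum)
    data.frame(level = names(signed), signed = as.numeric(signed),
               absolute = as.numeric(absolute), row.names = NULL)
  }
  up_total <- sum(abs(genes$delta[genes$direction == "up"]))
  down_total <- sum(abs(genes$delta[genes$direction == "down"]))
  structure(list(genes = genes,
                 by_direction = agg("direction"),
                 by_category = agg("category"),
                 up_total = up_total, down_total = down_total,
                 ratio_up_down = if (down_total > 0) up_total / down_total
                                 else NA_real_,
                 excluded = attr(table, "excluded")),
            class = "MassContributionSet")
}

#' @export
print.MassContributionSet <- function(x, ...) {
  cat(sprintf("Proteome mass contributions: %d genes\n", nrow(x$genes)))
  cat(sprintf("  up-total %.4g fg, down-total %.4g fg, ratio %.3g\n",
              x$up_total, x$down_total, x$ratio_up_down))
  if (length(x$excluded))
    cat("  excluded (r_wt = 0):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Pareto summary of mass contributions
#'
#' Ranks genes by |delta| (descending, ties by id) and reports the
#' cumulative percent of the total absolute mass change, highlighting the
#' `top_n` largest contributors — the usual few-genes-carry-most-of-the-
#' budget picture.
#'
#' @param contributions a `MassContributionSet`.
#' @param top_n how many top genes to return in the head table (default 20).
#' @return list: `table` (all genes: id, delta, abs_delta, rank,
#'   cumulative_pct), `top` (first `top_n` rows), `top_n_share_pct`
#'   (cumulative percent at rank `top_n`).
#' @export
pareto_summary <- function(contributions, top_n = 20) {
  stopifnot(inherits(contributions, "MassContributionSet"))
  g <- contributions$genes
  if (!nrow(g)) stop("no contributions to summarize")
  tab <- data.frame(id = g$id, delta = g$delta, abs_delta = abs(g$delta),
                    rank = g$rank, cumulative_pct = 100 * g$cumulative_frac)
  k <- min(top_n, nrow(tab))
  list(table = tab, top = tab[seq_len(k), , drop = FALSE],
       top_n_share_pct = tab$cumulative_pct[k])
}
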