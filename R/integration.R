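#' Parameters for ChIP/RNA integration
#'
#' `se_fc_min` is the directional linear fold change a differential
#' super-enhancer must reach (default 1: any significant directional change
#' passes; set it higher for stricter readings). `rna_fc_min` is the linear
#' fold-change screen applied to the expression table (default 1.2).
#'
#' @param se_fc_min linear fold-change minimum for SEs, >= 1 (default 1).
#' @param rna_fc_min linear fold-change minimum for RNA, >= 1 (default 1.2).
#' @param gene_window maximum SE-to-TSS distance in bases (default 100000).
#' @param require_concordance keep only direction-matched pairs (default
#'   TRUE).
#' @return list of class `integration_params`.
#' @export
integration_params <- function(se_fc_min = 1, rna_fc_min = 1.2,
                               gene_window = 100000,
                               require_concordance = TRUE) {
  stopifnot(se_fc_min >= 1, rna_fc_min >= 1, gene_window > 0)
  structure(list(se_fc_min = se_fc_min, rna_fc_min = rna_fc_min,
                 gene_window = gene_window,
                 require_concordance = require_concordance),
            class = "integration_params")
}

#' Integrate differential super-enhancers with differential expression
#'
#' Each differential SE is assigned its nearest gene (nearest TSS to the SE
#' midpoint, within `gene_window`); when several SEs land on one gene only
#' the highest-signal one is kept. An SE passes when its directional linear
#' fold change reaches `se_fc_min`; a gene passes when its expression fold
#' change reaches `rna_fc_min` (up) or `1/rna_fc_min` (down). A pair is
#' concordant when the SE and RNA directions match and neither is `ns`; with
#' `require_concordance` only concordant pairs are returned.
#'
#' Genes assigned an SE but absent from `de_table` are excluded and listed in
#' the `unmatched` attribute of the result.
#'
#' @param diff_ses data.frame of differential SEs: `se_id`, `chrom`, `start`,
#'   `end`, `signal` (ranking signal for best-SE-per-gene selection),
#'   `log2fc`, `p_value`, `call` (`up`/`down`/`ns`, as from
#'   [classify_regions()]).
#' @param annotation a [genome_annotation()].
#' @param de_table data.frame keyed by `gene_id` with `fold_change`,
#'   `p_value` and optionally `direction` (derived from `fold_change` vs
#'   `rna_fc_min` when absent).
#' @param params an [integration_params()].
#' @return data.frame sorted by `|se_log2fc|` descending: `gene_id`, `se_id`,
#'   `chrom`, `se_start`, `se_end`, `distance`, `se_log2fc`, `se_p`,
#'   `se_direction`, `rna_fold_change`, `rna_p`, `rna_direction`,
#'   `concordant`; attribute `unmatched` lists gene_ids missing from
#'   `de_table`.
#' @export
integrate_se_genes <- function(diff_ses, annotation, de_table,
                               params = integration_params()) {
  stopifnot(inherits(params, "integration_params"),
            inherits(annotation, "genome_annotation"))
  need <- c("se_id", "chrom", "start", "end", "signal", "log2fc", "p_value",
            "call")
  if (!all(need %in% names(diff_ses)))
    stop("diff_ses must have columns: ", paste(need, collapse = ", "))
  if (!all(c("gene_id", "fold_change") %in% names(de_table)))
    stop("de_table must have columns gene_id and fold_change")

  empty <- data.frame(gene_id = character(), se_id = character(),
                      chrom = character(), se_start = numeric(),
                      se_end = numeric(), distance = numeric(),
                      se_log2fc = numeric(), se_p = numeric(),
                      se_direction = character(), rna_fold_change = numeric(),
                      rna_p = numeric(), rna_direction = character(),
                      concordant = logical(), stringsAsFactors = FALSE)
  if (nrow(diff_ses) == 0L) {
    attr(empty, "unmatched") <- character()
    return(empty)
  }

  # (1) nearest gene per SE, within the gene window
  ng <- nearest_gene(diff_ses[, c("chrom", "start", "end")], annotation)
  assoc <- cbind(diff_ses, ng)
  assoc <- assoc[abs(assoc$distance) <= params$gene_window, , drop = FALSE]

  # (2) one SE per gene: the highest-signal one (ties toward leftmost start)
  if (nrow(assoc) > 1L) {
    assoc <- assoc[order(assoc$gene_id, -assoc$signal, assoc$start), ,
                   drop = FALSE]
    assoc <- assoc[!duplicated(assoc$gene_id), , drop = FALSE]
  }

  # (3) SE directional fold-change threshold
  se_lin_fc <- ifelse(assoc$call == "up", 2^assoc$log2fc, 2^(-assoc$log2fc))
  assoc <- assoc[assoc$call %in% c("up", "down") & se_lin_fc >= params$se_fc_min, ,
                 drop = FALSE]

  # (4) join the expression table
  unmatched <- setdiff(assoc$gene_id, de_table$gene_id)
  assoc <- assoc[assoc$gene_id %in% de_table$gene_id, , drop = FALSE]
  de <- de_table[match(assoc$gene_id, de_table$gene_id), , drop = FALSE]
  rna_fc <- de$fold_change
  rna_p <- if (is.null(de$p_value)) rep(NA_real_, nrow(de)) else de$p_value
  rna_dir <- if (!is.null(de$direction)) as.character(de$direction) else
    ifelse(rna_fc >= params$rna_fc_min, "up",
    ifelse(rna_fc <= 1 / params$rna_fc_min, "down", "ns"))
  rna_pass <- (rna_dir == "up" & rna_fc >= params$rna_fc_min) |
              (rna_dir == "down" & rna_fc <= 1 / params$rna_fc_min)

  out <- data.frame(gene_id = assoc$gene_id, se_id = assoc$se_id,
                    chrom = assoc$chrom, se_start = assoc$start,
                    se_end = assoc$end, distance = assoc$distance,
                    se_log2fc = assoc$log2fc, se_p = assoc$p_value,
                    se_direction = as.character(assoc$call),
                    rna_fold_change = rna_fc, rna_p = rna_p,
                    rna_direction = rna_dir,
                    concordant = rna_pass &
                      as.character(assoc$call) == rna_dir,
                    stringsAsFactors = FALSE)
  out <- out[rna_pass, , drop = FALSE]
  if (params$require_concordance)
    out <- out[out$concordant, , drop = FALSE]
  out <- out[order(-abs(out$se_log2fc), out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmatched") <- unmatched
  out
}

#' Summarize concordant SE-gene associations
#'
#' @param associations output of [integrate_se_genes()].
#' @return list with `n_total`, `n_up`, `n_down` over concordant
#'   associations (`n_total = n_up + n_down`).
#' @export
summarize_integration <- function(associations) {
  conc <- associations[associations$concordant, , drop = FALSE]
  n_up <- sum(conc$se_direction == "up")
  n_down <- sum(conc$se_direction == "down")
  list(n_total = n_up + n_down, n_up = n_up, n_down = n_down)
}
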