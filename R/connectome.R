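# Synapse-table analyses: partner selection, input-selectivity
# classification, contra/ipsi profiles, branch-count test, Ward clustering.

#' Synapse table constructor/validator
#'
#' @param records data.frame with columns `pre_id`, `pre_type`, `post_id`,
#'   `post_type`, `roi`, `side` (one of `"ipsi"`, `"contra"`, `"unknown"`),
#'   `weight` (synapse count, positive integer).
#' @return the validated data.frame with class `synapse_table`.
#' @export
synapse_table <- function(records) {
  need <- c("pre_id", "pre_type", "post_id", "post_type", "roi", "side",
            "weight")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(records$side %in% c("ipsi", "contra", "unknown"))) {
    stop("side must be one of ipsi, contra, unknown")
  }
  w <- records$weight
  if (any(!is.finite(w)) || any(w < 1) || any(w != round(w))) {
    stop("weight must be a positive integer synapse count")
  }
  class(records) <- c("synapse_table", "data.frame")
  records
}

# sum of weights grouped by one or more columns
sum_by <- function(tab, by, value = "weight") {
  agg <- aggregate(tab[[value]], by = lapply(by, function(b) tab[[b]]),
                   FUN = sum)
  names(agg) <- c(by, value)
  agg
}

#' Select downstream partner cell types of a seed type
#'
#' Applies the synapse-count/relative-input inclusion rule: cell types with
#' at most 10 input synapses from the seed are excluded; types with more
#' than 50 are included irrespective of their relative input; types in
#' between are included when their relative input percentage lies strictly
#' above the line through (10 synapses, 4%) and (50 synapses, 0.5%), i.e.
#' `p(s) = 4 - 0.0875 * (s - 10)` percent.
#'
#' @param table a [synapse_table()].
#' @param seed_type pre-synaptic cell type whose downstream partners are
#'   selected.
#' @param roi_filter optional character vector of ROIs; seed outputs outside
#'   these ROIs are ignored.
#' @param totals optional named numeric vector of total input synapses per
#'   downstream cell type (across all presynaptic partners); computed from
#'   `table` when omitted.
#' @return data.frame with one row per downstream type: `post_type`,
#'   `synapses`, `total_inputs`, `fraction_pct`, `decision`, `rule`.
#' @export
select_downstream_types <- function(table, seed_type, roi_filter = NULL,
                                    totals = NULL) {
  stopifnot(inherits(table, "synapse_table"))
  sel <- table[table$pre_type == seed_type, , drop = FALSE]
  if (!is.null(roi_filter)) sel <- sel[sel$roi %in% roi_filter, , drop = FALSE]
  if (nrow(sel) == 0) stop("no outputs of the seed type in the table")
  if (is.null(totals)) {
    tot <- sum_by(as.data.frame(table), "post_type")
    totals <- setNames(tot$weight, tot$post_type)
  }
  per_type <- sum_by(as.data.frame(sel), "post_type")
  if (any(!per_type$post_type %in% names(totals))) {
    stop("missing total input counts for some downstream types")
  }
  s <- per_type$weight
  total_inputs <- unname(totals[per_type$post_type])
  pct <- s / total_inputs * 100
  line <- 4 - 0.0875 * (s - 10)
  decision <- ifelse(s <= 10, "exclude",
                     ifelse(s >= 51, "include",
                            ifelse(pct > line, "include", "exclude")))
  rule <- ifelse(s <= 10, "at most 10 synapses",
                 ifelse(s >= 51, "more than 50 synapses",
                        ifelse(pct > line, "above boundary line",
                               "below boundary line")))
  out <- data.frame(post_type = per_type$post_type, synapses = s,
                    total_inputs = total_inputs, fraction_pct = pct,
                    decision = decision, rule = rule)
  out[order(-out$synapses), , drop = FALSE]
}

#' Classify the input selectivity of a cell type
#'
#' Partners contributing more than 0.5% of the cell type's input synapses
#' or more than 10 synapses are considered. The type is `multimodal` when
#' its considered sensory-pathway input exceeds 25% of its considered
#' olfactory input from uniglomerular PNs; otherwise `DA1-selective` when
#' DA1 PNs provide more than 50% of the olfactory input, else
#' `mixed-olfactory`. With zero olfactory input the type is
#' `unclassifiable`.
#'
#' @param table a [synapse_table()].
#' @param cell_type post-synaptic type to classify.
#' @param pathway_labels data.frame mapping `pre_type` to `pathway` (one of
#'   `"uniglomerular-PN"`, `"sensory"`, `"other"`) and, for PNs,
#'   `glomerulus`.
#' @return list of class `input_classification`: the class plus olfactory,
#'   DA1 and sensory synapse counts among considered partners.
#' @export
classify_input_selectivity <- function(table, cell_type, pathway_labels) {
  stopifnot(inherits(table, "synapse_table"),
            all(c("pre_type", "pathway") %in% names(pathway_labels)))
  inp <- table[table$post_type == cell_type, , drop = FALSE]
  if (nrow(inp) == 0) stop("no inputs to this cell type in the table")
  per <- sum_by(as.data.frame(inp), "pre_type")
  total <- sum(per$weight)
  considered <- per[per$weight / total > 0.005 | per$weight > 10, ,
                    drop = FALSE]
  lab <- pathway_labels[match(considered$pre_type,
                              pathway_labels$pre_type), , drop = FALSE]
  if (any(is.na(lab$pathway))) {
    stop("unlabeled presynaptic types: ",
         paste(considered$pre_type[is.na(lab$pathway)], collapse = ", "))
  }
  olf <- sum(considered$weight[lab$pathway == "uniglomerular-PN"])
  sens <- sum(considered$weight[lab$pathway == "sensory"])
  da1 <- if (is.null(lab$glomerulus)) 0 else {
    sum(considered$weight[lab$pathway == "uniglomerular-PN" &
                            !is.na(lab$glomerulus) & lab$glomerulus == "DA1"])
  }
  cls <- if (olf == 0) {
    "unclassifiable"
  } else if (sens > 0.25 * olf) {
    "multimodal"
  } else if (da1 > 0.5 * olf) {
    "DA1-selective"
  } else {
    "mixed-olfactory"
  }
  structure(list(cell_type = cell_type, class = cls,
                 olfactory_input = olf, da1_input = da1,
                 sensory_input = sens, total_input = total),
            class = "input_classification")
}

#' @export
print.input_classification <- function(x, ...) {
  cat(sprintf("%s: %s (olfactory %d, DA1 %d, sensory %d of %d inputs)\n",
              x$cell_type, x$class, x$olfactory_input, x$da1_input,
              x$sensory_input, x$total_input))
  invisible(x)
}

#' Per-glomerulus contra/ipsi ORN-input profile of a local interneuron
#'
#' For each glomerulus, computes the ratio of contralateral to ipsilateral
#' ORN input synapses onto `ln_type`, the fraction of the interneuron's
#' output synapses that target that glomerulus's uniglomerular PNs, and the
#' contralateral ORN input count. ORN and PN types are matched by name
#' prefix, with the glomerulus taken from the suffix (e.g. `ORN_DA1`,
#' `PN_DA1`). Glomeruli whose ORN records carry an `unknown` side label are
#' dropped with a warning; ratios with zero ipsilateral input are flagged
#' `NA` rather than infinite.
#'
#' @param table a [synapse_table()].
#' @param ln_type the local interneuron type.
#' @param orn_prefix,pn_prefix type-name prefixes encoding the glomerulus.
#' @return data.frame: `glomerulus`, `contra`, `ipsi`, `ratio`,
#'   `pn_output_fraction`, `ratio_defined`.
#' @export
contra_ipsi_profile <- function(table, ln_type, orn_prefix = "ORN_",
                                pn_prefix = "PN_") {
  stopifnot(inherits(table, "synapse_table"))
  orn_in <- table[table$post_type == ln_type &
                    startsWith(table$pre_type, orn_prefix), , drop = FALSE]
  if (nrow(orn_in) == 0) stop("no ORN inputs to the interneuron type")
  if (all(orn_in$side == "unknown")) stop("no side-labeled records")
  glom <- substring(orn_in$pre_type, nchar(orn_prefix) + 1)
  unknown_gloms <- unique(glom[orn_in$side == "unknown"])
  if (length(unknown_gloms) > 0) {
    warning("dropping glomeruli with missing ORN side information: ",
            paste(sort(unknown_gloms), collapse = ", "))
  }
  keep <- !(glom %in% unknown_gloms)
  orn_in <- orn_in[keep, , drop = FALSE]
  glom <- glom[keep]
  gloms <- sort(unique(glom))
  contra <- vapply(gloms, function(g)
    sum(orn_in$weight[glom == g & orn_in$side == "contra"]), 1)
  ipsi <- vapply(gloms, function(g)
    sum(orn_in$weight[glom == g & orn_in$side == "ipsi"]), 1)
  out_tab <- table[table$pre_type == ln_type, , drop = FALSE]
  out_total <- sum(out_tab$weight)
  pn_frac <- vapply(gloms, function(g) {
    if (out_total == 0) return(NA_real_)
    sum(out_tab$weight[out_tab$post_type == paste0(pn_prefix, g)]) / out_total
  }, 1)
  data.frame(glomerulus = gloms, contra = contra, ipsi = ipsi,
             ratio = ifelse(ipsi > 0, contra / ipsi, NA_real_),
             pn_output_fraction = pn_frac,
             ratio_defined = ipsi > 0, row.names = NULL)
}

#' One-sample t test of branch counts against 1
#'
#' Tests whether a sample of per-neuron branch counts differs from 1 (the
#' single-branch default). Zero-variance samples are handled exactly: p = 1
#' when all counts equal 1, p = 0 otherwise.
#'
#' @param counts integer vector of branch counts, length >= 2.
#' @return list of class `stat_report`: mean, sd, t statistic, df, p-value.
#' @export
branch_count_test <- function(counts) {
  stopifnot(length(counts) >= 2, all(is.finite(counts)))
  m <- mean(counts)
  s <- sd(counts)
  n <- length(counts)
  if (s == 0) {
    res <- list(statistic = if (m == 1) 0 else Inf * sign(m - 1),
                p_value = if (m == 1) 1 else 0)
  } else {
    tt <- t.test(counts, mu = 1)
    res <- list(statistic = unname(tt$statistic), p_value = tt$p.value)
  }
  structure(list(test = "one-sample t-test vs 1",
                 statistic = res$statistic, p_value = res$p_value,
                 mean = m, sd = s, df = n - 1, design = "one-sample"),
            class = "stat_report")
}

#' Ward clustering of a similarity matrix
#'
#' Converts a symmetric similarity matrix to a distance (`1 - s / max(s)`),
#' applies Ward linkage (`ward.D2`) and cuts the tree into `k` clusters.
#'
#' @param similarity square symmetric numeric matrix; larger means more
#'   similar.
#' @param k number of clusters (default 3).
#' @return integer cluster labels named by the matrix rownames, with the
#'   `hclust` tree attached as attribute `"tree"`.
#' @export
ward_cluster <- function(similarity, k = 3) {
  similarity <- as.matrix(similarity)
  if (nrow(similarity) != ncol(similarity)) stop("non-square input")
  if (max(abs(similarity - t(similarity))) > 1e-8) {
    stop("similarity matrix must be symmetric")
  }
  stopifnot(k >= 1, k <= nrow(similarity))
  d <- 1 - similarity / max(similarity)
  tree <- hclust(as.dist(d), method = "ward.D2")
  labels <- cutree(tree, k = k)
  attr(labels, "tree") <- tree
  labels
}

#' Compare two clusterings up to label permutation
#'
#' @param a,b integer label vectors of equal length.
#' @return TRUE when the two labelings induce the same partition.
#' @export
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  ta <- outer(a, a, "==")
  tb <- outer(b, b, "==")
  all(ta == tb)
}
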