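#' Precision and recall of a retrieval result
#'
#' `P = N_R / (N_R + N_I)` and `R = N_R / T_R`, where `N_R` is the number
#' of relevant images retrieved, `N_I` the number of irrelevant images
#' retrieved, and `T_R` the total number of relevant images in the
#' database.
#'
#' @param retrieved_ids Character vector of retrieved ids (ranked or
#'   not), or a `query_result`.
#' @param relevant_ids Character vector (set) of relevant ids.
#' @param T_R Total number of relevant images in the database (>= 1).
#' @return List with `precision` and `recall`.
#' @export
precision_recall <- function(retrieved_ids, relevant_ids, T_R) {
  if (inherits(retrieved_ids, "query_result"))
    retrieved_ids <- retrieved_ids$ranked$id
  if (T_R < 1) stop("T_R must be >= 1")
  if (length(retrieved_ids) == 0L) stop("empty retrieval result")
  n_r <- sum(retrieved_ids %in% relevant_ids)
  n_i <- length(retrieved_ids) - n_r
  list(precision = n_r / (n_r + n_i), recall = n_r / T_R)
}

#' Interpolated precision-recall curve on a fixed recall grid
#'
#' Walks the ranking over all cutoffs; at each grid level `r`, precision
#' is the maximum precision over cutoffs achieving recall at least `r`
#' (standard interpolated precision). Levels never reached get
#' precision 0.
#'
#' @param ranked_ids Ranked character vector of retrieved ids, or a
#'   `query_result`.
#' @param relevant_ids Set of relevant ids.
#' @param T_R Total relevant count in the database.
#' @param grid Ascending recall levels (default `0.1, ..., 1.0`).
#' @return data.frame with columns `recall` and `precision`.
#' @export
pr_curve <- function(ranked_ids, relevant_ids, T_R,
                     grid = seq(0.1, 1, 0.1)) {
  if (inherits(ranked_ids, "query_result"))
    ranked_ids <- ranked_ids$ranked$id
  if (T_R < 1) stop("T_R must be >= 1")
  hits <- cumsum(ranked_ids %in% relevant_ids)
  cut_prec <- hits / seq_along(ranked_ids)
  cut_rec <- hits / T_R
  prec <- vapply(grid, function(r) {
    ok <- cut_rec >= r
    if (any(ok)) max(cut_prec[ok]) else 0
  }, numeric(1L))
  data.frame(recall = grid, precision = prec)
}

#' Area under a precision-recall curve
#'
#' Trapezoidal integral over `[0, 1]`; the first grid value is extended
#' back to recall 0.
#'
#' @param curve data.frame with ascending `recall` and `precision`
#'   columns (e.g. from [pr_curve] or a mean curve).
#' @return Scalar AUC in `[0, 1]`.
#' @export
pr_auc <- function(curve) {
  if (is.null(curve) || nrow(curve) == 0L) stop("empty curve")
  r <- curve$recall; p <- curve$precision
  auc <- r[1L] * p[1L]
  if (length(r) > 1L)
    auc <- auc + sum(diff(r) * (utils::head(p, -1L) + utils::tail(p, -1L)) / 2)
  auc
}

#' Evaluate a set of queries against an index
#'
#' Relevance is sharing the query's category label. Returns per-query
#' interpolated PR curves, the macro-averaged mean curve on the recall
#' grid, its AUC, precision at `k`, and a per-category breakdown.
#'
#' @param index An `image_index` with labels.
#' @param queries List of labeled [gray_image] queries (or synthetic
#'   dataset records).
#' @param k Retrieval depth for `precision_at_k` (default 10).
#' @param mode `"linear"` or `"hashed"`.
#' @param grid Recall grid.
#' @return Object of class `eval_report`: `per_query` (data.frame),
#'   `mean_curve`, `auc`, `precision_at_k`, `per_category`,
#'   `config_fingerprint`.
#' @export
evaluate_queries <- function(index, queries, k = 10L,
                             mode = c("linear", "hashed"),
                             grid = seq(0.1, 1, 0.1)) {
  mode <- match.arg(mode)
  if (!is.null(queries[[1L]]$image))
    queries <- lapply(queries, function(rec) rec$image)
  if (all(is.na(index$labels))) stop("index has no labels")
  n_db <- length(index$ids)
  rows <- lapply(queries, function(qimg) {
    label <- qimg$label
    relevant <- index$ids[!is.na(index$labels) & index$labels == label]
    if (length(relevant) == 0L)
      stop("no relevant records for query ", qimg$id, " (label ", label, ")")
    res <- if (mode == "linear") query_linear(index, qimg, k = n_db)
           else query_hashed(index, qimg, k = n_db,
                             max_radius = index$config$b)
    curve <- pr_curve(res, relevant, T_R = length(relevant), grid = grid)
    pk <- precision_recall(res$ranked$id[seq_len(min(k, nrow(res$ranked)))],
                           relevant, T_R = length(relevant))$precision
    list(id = qimg$id, label = label, curve = curve, p_at_k = pk)
  })
  curves <- vapply(rows, function(x) x$curve$precision,
                   numeric(length(grid)))
  mean_curve <- data.frame(recall = grid, precision = rowMeans(curves))
  per_query <- data.frame(
    id = vapply(rows, `[[`, character(1L), "id"),
    label = vapply(rows, `[[`, character(1L), "label"),
    precision_at_k = vapply(rows, `[[`, numeric(1L), "p_at_k"),
    stringsAsFactors = FALSE)
  per_category <- stats::aggregate(
    precision_at_k ~ label, data = per_query, FUN = mean)
  structure(
    list(per_query = per_query, mean_curve = mean_curve,
         auc = pr_auc(mean_curve),
         precision_at_k = mean(per_query$precision_at_k), k = as.integer(k),
         per_category = per_category,
         config_fingerprint = index$fingerprint),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d queries, AUC %.4f, precision@%d %.4f\n",
              nrow(x$per_query), x$auc, x$k, x$precision_at_k))
  invisible(x)
}

# split a labeled dataset into index and query records per category
split_dataset <- function(dataset, n_query_per_cat = 5L) {
  labels <- vapply(dataset, function(rec) rec$image$label, character(1L))
  qidx <- unlist(lapply(split(seq_along(dataset), labels), function(ii)
    ii[seq_len(min(n_query_per_cat, max(length(ii) - 1L, 1L)))]))
  list(index = dataset[-qidx], queries = dataset[qidx])
}

# codes (nc_i, nc_s) for a list of records through a fitted mean image
dataset_codes <- function(records, config, mean_image) {
  lapply(records, function(rec) {
    sq <- image_squares(rec$image, config)
    list(nc_i = extract_codes(to_net_input(sq$whole, mean_image),
                              config$extractor),
         nc_s = extract_codes(to_net_input(sq$salient, mean_image),
                              config$extractor))
  })
}

# precision@k of linear cosine retrieval given fused descriptor matrices
sweep_precision <- function(D_index, D_query, index_labels, query_labels,
                            index_ids, k = 10L, grid = seq(0.1, 1, 0.1)) {
  p_at_k <- numeric(nrow(D_query))
  p_at_r1 <- numeric(nrow(D_query))
  for (i in seq_len(nrow(D_query))) {
    sims <- similarity_rows(D_index, D_query[i, ])
    ord <- order(-sims, index_ids)
    relevant <- index_ids[index_labels == query_labels[i]]
    ranked <- index_ids[ord]
    p_at_k[i] <- precision_recall(ranked[seq_len(min(k, length(ranked)))],
                                  relevant, length(relevant))$precision
    p_at_r1[i] <- pr_curve(ranked, relevant, length(relevant),
                           grid = grid)$precision[1L]
  }
  c(precision_at_k = mean(p_at_k), precision_at_recall_01 = mean(p_at_r1))
}

#' Fusion-weight sweep
#'
#' Re-fuses precomputed whole/salient codes at each `(alpha, 1 - alpha)`
#' pair, refits the normalizer on the index split, and reports mean
#' precision@`k` and mean interpolated precision at recall 0.1 over the
#' query split. Codes are computed once, so the sweep isolates the effect
#' of the fusion weights.
#'
#' @param dataset Labeled synthetic dataset (from [generate_dataset]).
#' @param alphas Weight grid (default `0, 0.2, 0.4, 0.6, 0.8, 1`).
#' @param config A [pipeline_config] (its alpha/beta are overridden by
#'   the sweep).
#' @param n_query_per_cat Queries held out per category.
#' @param k Retrieval depth.
#' @return data.frame with columns `alpha`, `beta`, `precision_at_k`,
#'   `precision_at_recall_01`.
#' @export
fusion_sweep <- function(dataset, alphas = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                         config = pipeline_config(),
                         n_query_per_cat = 5L, k = 10L) {
  sp <- split_dataset(dataset, n_query_per_cat)
  idx_sq <- lapply(sp$index, function(rec)
    rescale_and_pad(rec$image, config$T_side)$square)
  mean_image <- compute_mean_image(idx_sq)
  codes_idx <- dataset_codes(sp$index, config, mean_image)
  codes_q <- dataset_codes(sp$queries, config, mean_image)
  lab_idx <- vapply(sp$index, function(rec) rec$image$label, character(1L))
  lab_q <- vapply(sp$queries, function(rec) rec$image$label, character(1L))
  ids_idx <- vapply(sp$index, function(rec) rec$image$id, character(1L))
  out <- lapply(alphas, function(a) {
    Fi <- do.call(rbind, lapply(codes_idx, function(cd)
      as.numeric(fuse(cd$nc_i, cd$nc_s, a, 1 - a))))
    Fq <- do.call(rbind, lapply(codes_q, function(cd)
      as.numeric(fuse(cd$nc_i, cd$nc_s, a, 1 - a))))
    nrm <- fit_normalizer(Fi, mode = config$norm_mode)
    Di <- do.call(rbind, lapply(seq_len(nrow(Fi)), function(i)
      normalize_descriptor(Fi[i, ], nrm)))
    Dq <- do.call(rbind, lapply(seq_len(nrow(Fq)), function(i)
      normalize_descriptor(Fq[i, ], nrm)))
    pr <- sweep_precision(Di, Dq, lab_idx, lab_q, ids_idx, k = k,
                          grid = config$recall_grid)
    data.frame(alpha = a, beta = 1 - a,
               precision_at_k = pr[["precision_at_k"]],
               precision_at_recall_01 = pr[["precision_at_recall_01"]])
  })
  do.call(rbind, out)
}

#' Noise-robustness sweep
#'
#' Corrupts query images (salt & pepper flip probability or zero-mean
#' Gaussian variance), optionally applies a 3x3 median filter before
#' feature extraction, and reports mean precision@`k` per condition.
#' Level 0 reproduces the clean baseline exactly. Noise is injected on
#' queries only; the index stays clean.
#'
#' @param index A labeled `image_index`.
#' @param queries List of labeled query records or [gray_image]s.
#' @param sp_levels Salt & pepper probabilities (default
#'   `0, 0.05, 0.1, 0.2`).
#' @param gauss_levels Gaussian variances in intensity units squared
#'   (default `25, 100, 400`).
#' @param k Retrieval depth.
#' @param seed Seed for the noise draws.
#' @return data.frame with columns `model`, `level`, `filtered`,
#'   `precision_at_k`, `seed`.
#' @export
noise_sweep <- function(index, queries, sp_levels = c(0, 0.05, 0.1, 0.2),
                        gauss_levels = c(25, 100, 400), k = 10L,
                        seed = 1L) {
  if (!is.null(queries[[1L]]$image))
    queries <- lapply(queries, function(rec) rec$image)
  conditions <- rbind(
    data.frame(model = "saltpepper", level = sp_levels),
    data.frame(model = "gaussian", level = gauss_levels))
  eval_cond <- function(model, level, filtered) {
    pk <- vapply(seq_along(queries), function(i) {
      qimg <- queries[[i]]
      noisy <- corrupt(qimg, model = model, level = level,
                       seed = seed + i)
      if (filtered) noisy <- median_filter3(noisy)
      relevant <- index$ids[!is.na(index$labels) &
                              index$labels == qimg$label]
      res <- query_linear(index, noisy, k = k)
      precision_recall(res$ranked$id, relevant,
                       T_R = length(relevant))$precision
    }, numeric(1L))
    mean(pk)
  }
  rows <- lapply(seq_len(nrow(conditions)), function(ci) {
    m <- conditions$model[ci]; lv <- conditions$level[ci]
    data.frame(model = m, level = lv, filtered = c(FALSE, TRUE),
               precision_at_k = c(eval_cond(m, lv, FALSE),
                                  eval_cond(m, lv, TRUE)),
               seed = seed)
  })
  do.call(rbind, rows)
}

#' 3x3 median filter
#'
#' @param img A [gray_image] or matrix.
#' @return Filtered object of the same type.
#' @export
median_filter3 <- function(img) {
  px <- if (inherits(img, "gray_image")) img$pixels else img
  out <- EBImage::medianFilter(px / 255, size = 1L) * 255
  out <- matrix(as.numeric(out), nrow(px), ncol(px))
  if (inherits(img, "gray_image"))
    gray_image(out, id = img$id, label = img$label)
  else out
}

#' Write an evaluation report to CSV and JSON
#'
#' @param report An `eval_report` or a sweep data.frame.
#' @param path_prefix Output prefix.
#' @return Written paths, invisibly.
#' @export
write_eval_report <- function(report, path_prefix) {
  csv <- paste0(path_prefix, ".csv"); js <- paste0(path_prefix, ".json")
  tab <- if (inherits(report, "eval_report")) report$mean_curve else report
  utils::write.csv(tab, csv, row.names = FALSE)
  jsonlite::write_json(report, js, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(c(csv, js))
}
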