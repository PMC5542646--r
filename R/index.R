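#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with defaults: preprocessing
#' side `T_side = 224`, saliency working side `r = 32` with bandwidth
#' `sigma_frac` of the working width, fusion weights `alpha = 0.4`,
#' `beta = 0.6`, the extractor configuration, descriptor normalization
#' mode, and the hashing parameters `rho = 300`, `t = 30`, `b = 128` with
#' a median-heuristic bandwidth unless `gamma` is given. `max_radius`
#' bounds the Hamming radius of hashed candidate expansion. `seed` drives
#' every stochastic stage.
#'
#' @param T_side,r,sigma_frac,alpha,beta,extractor,norm_mode Pipeline
#'   stage parameters (see above).
#' @param rho,t,b,gamma,eig_floor Hashing parameters (see [fit_klsh]).
#' @param max_radius Default candidate-expansion radius bound.
#' @param recall_grid Recall levels for evaluation curves.
#' @param seed Integer seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(T_side = 224L, r = 32L, sigma_frac = 0.1,
                            alpha = 0.4, beta = 0.6,
                            extractor = extractor_config(),
                            norm_mode = "global",
                            rho = 300L, t = 30L, b = 128L, gamma = NULL,
                            eig_floor = 1e-12, max_radius = 16L,
                            recall_grid = seq(0.1, 1, 0.1), seed = 1L) {
  if (abs(alpha + beta - 1) > 1e-12 || alpha < 0 || beta < 0)
    stop("alpha and beta must be non-negative and sum to 1")
  if (r * r > 2304L) stop("r^2 must not exceed 2304")
  cfg <- list(T_side = as.integer(T_side), r = as.integer(r),
              sigma_frac = sigma_frac, alpha = alpha, beta = beta,
              extractor = extractor, norm_mode = norm_mode,
              rho = as.integer(rho), t = as.integer(t), b = as.integer(b),
              gamma = gamma, eig_floor = eig_floor,
              max_radius = as.integer(max_radius),
              recall_grid = recall_grid, seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

config_fingerprint <- function(config) {
  flat <- unlist(config[c("T_side", "r", "sigma_frac", "alpha", "beta",
                          "norm_mode", "rho", "t", "b", "max_radius",
                          "seed")])
  ex <- config$extractor
  paste0(paste(names(flat), flat, sep = "=", collapse = ";"),
         ";backbone=", ex$backbone, ";g=", ex$g, ";o=", ex$o)
}

# whole-image square + salient-region square for one image
image_squares <- function(img, config) {
  S <- saliency_map(img, r = config$r, sigma_frac = config$sigma_frac)
  list(whole = rescale_and_pad(img, config$T_side),
       salient = rescale_and_pad(salient_crop(extract_salient(img, S)),
                                 config$T_side))
}

# descriptor of one image through fitted index components
query_descriptor <- function(index, img) {
  sq <- image_squares(img, index$config)
  nc_i <- extract_codes(to_net_input(sq$whole, index$mean_image),
                        index$config$extractor)
  nc_s <- extract_codes(to_net_input(sq$salient, index$mean_image),
                        index$config$extractor)
  normalize_descriptor(
    fuse(nc_i, nc_s, index$config$alpha, index$config$beta),
    index$normalizer)
}

#' Build a retrieval index over a set of images
#'
#' Runs the full pipeline per image (preprocess, saliency, whole and
#' salient codes, fusion), fits the min-max normalizer and the hashing
#' model on the resulting descriptors, hashes every record and groups
#' records into hash buckets. The mean image is computed over the index
#' set's preprocessed squares and persisted for query-time reuse.
#' `rho` is capped at the collection size.
#'
#' @param images List of [gray_image] objects (labels optional), or a
#'   synthetic dataset from [generate_dataset].
#' @param config A [pipeline_config].
#' @param progress Print per-stage progress to stderr.
#' @return Object of class `image_index`: `ids`, `labels`, `descriptors`
#'   (matrix, one row per record), `keys` (matrix of bits), `buckets`,
#'   `normalizer`, `klsh`, `mean_image`, `config`, `fingerprint`.
#' @export
build_index <- function(images, config = pipeline_config(),
                        progress = FALSE) {
  if (length(images) == 0L) stop("empty image collection")
  if (!is.null(images[[1L]]$image))  # synthetic dataset records
    images <- lapply(images, function(rec) rec$image)
  ids <- vapply(images, function(im) im$id, character(1L))
  if (anyDuplicated(ids)) stop("image ids must be unique")
  labels <- vapply(images, function(im)
    if (is.null(im$label)) NA_character_ else im$label, character(1L))
  note <- function(...) if (progress) message(...)

  note("preprocess + saliency: ", length(images), " images")
  squares <- lapply(images, image_squares, config = config)
  mean_image <- compute_mean_image(lapply(squares, function(s)
    s$whole$square))

  note("feature extraction")
  codes <- lapply(squares, function(sq) {
    list(nc_i = extract_codes(to_net_input(sq$whole, mean_image),
                              config$extractor),
         nc_s = extract_codes(to_net_input(sq$salient, mean_image),
                              config$extractor))
  })
  fused <- do.call(rbind, lapply(codes, function(cd)
    as.numeric(fuse(cd$nc_i, cd$nc_s, config$alpha, config$beta))))

  note("normalizer + hashing fit")
  normalizer <- fit_normalizer(fused, mode = config$norm_mode)
  descs <- do.call(rbind, lapply(seq_len(nrow(fused)), function(i)
    normalize_descriptor(fused[i, ], normalizer)))
  klsh <- fit_klsh(descs, rho = min(config$rho, nrow(descs)),
                   t = min(config$t, min(config$rho, nrow(descs))),
                   b = config$b, seed = config$seed, gamma = config$gamma,
                   eig_floor = config$eig_floor)
  keys <- klsh_hash(klsh, descs)
  key_strings <- apply(keys, 1L, key_string)
  buckets <- split(seq_along(ids), key_strings)

  structure(
    list(ids = ids, labels = labels, descriptors = descs, keys = keys,
         key_strings = key_strings, buckets = buckets,
         normalizer = normalizer, klsh = klsh, mean_image = mean_image,
         config = config, fingerprint = config_fingerprint(config)),
    class = "image_index")
}

#' @export
print.image_index <- function(x, ...) {
  cat(sprintf("<image_index> %d records, %d-bit keys, %d buckets\n",
              length(x$ids), ncol(x$keys), length(x$buckets)))
  invisible(x)
}

#' Save / load an index
#'
#' The index (descriptors, keys, buckets, normalizer, hashing model, mean
#' image and configuration fingerprint) is persisted as a single RDS
#' container.
#'
#' @param index An `image_index`.
#' @param path Destination path.
#' @return `path` (save) or the restored `image_index` (load).
#' @export
save_index <- function(index, path) {
  saveRDS(index, path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  index <- readRDS(path)
  if (!inherits(index, "image_index")) stop("not an image_index container")
  index
}

#' Cosine similarity between normalized descriptors
#'
#' On min-max-normalized (hence non-negative) descriptors the cosine lies
#' in `[0, 1]`; identical vectors score exactly 1 and the zero vector
#' scores 0 against anything.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
similarity <- function(x, y) {
  if (length(x) != length(y)) stop("vector lengths differ")
  if (identical(as.numeric(x), as.numeric(y)) && any(x != 0)) return(1)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  min(max(sum(x * y) / (nx * ny), 0), 1)
}

# similarities of one query descriptor against rows of a matrix
similarity_rows <- function(D, q) {
  qn <- sqrt(sum(q^2))
  if (qn == 0) return(numeric(nrow(D)))
  dn <- sqrt(rowSums(D^2))
  s <- as.numeric(D %*% q) / (dn * qn)
  s[dn == 0] <- 0
  s <- pmin(pmax(s, 0), 1)
  s[apply(D, 1L, function(r) identical(as.numeric(r), as.numeric(q))) &
      qn > 0] <- 1
  s
}

#' Linear-scan query
#'
#' Computes the query descriptor through the index's fitted components,
#' scores every record with [similarity], and returns the top `k`
#' (ties broken by ascending id).
#'
#' @param index An `image_index`.
#' @param img Query [gray_image].
#' @param k Number of results (capped at the index size).
#' @return A `query_result` with `ranked` (data.frame of `id`, `sim`),
#'   `k`, `mode = "linear"`, `candidates_examined = index size`.
#' @export
query_linear <- function(index, img, k = 10L) {
  if (length(index$ids) == 0L) stop("empty index")
  if (k < 1L) stop("k must be >= 1")
  q <- query_descriptor(index, img)
  sims <- similarity_rows(index$descriptors, q)
  order_result(index, sims, seq_along(index$ids), k, "linear",
               length(index$ids))
}

order_result <- function(index, sims, idx, k, mode, examined) {
  ord <- order(-sims, index$ids[idx])
  take <- ord[seq_len(min(k, length(idx)))]
  structure(
    list(ranked = data.frame(id = index$ids[idx][take], sim = sims[take],
                             stringsAsFactors = FALSE),
         k = as.integer(k), mode = mode,
         candidates_examined = as.integer(examined)),
    class = "query_result")
}

#' @export
print.query_result <- function(x, ...) {
  cat(sprintf("<query_result> mode=%s, %d results, %d candidates examined\n",
              x$mode, nrow(x$ranked), x$candidates_examined))
  print(utils::head(x$ranked, 10L))
  invisible(x)
}

#' Hash-bucket query with radius-ordered candidate expansion
#'
#' The query key is computed through the index's hashing model;
#' candidate records are gathered bucket-by-bucket in increasing Hamming
#' radius (0, 1, 2, ...) until at least `3 k` candidates are collected or
#' the radius exceeds `max_radius` (each started radius is completed, so
#' the candidate set equals a brute-force Hamming scan at the final
#' cutoff). Candidates are then reranked by [similarity]. A `max_radius`
#' of `b` or more disables the early stop entirely: the candidate pool is
#' the whole index and the ranking is identical to [query_linear].
#'
#' @param index An `image_index`.
#' @param img Query [gray_image].
#' @param k Number of results.
#' @param max_radius Radius bound; `b` makes the search exhaustive and
#'   equal to [query_linear].
#' @return A `query_result` with `mode = "hashed"` and
#'   `candidates_examined` = number of candidates gathered.
#' @export
query_hashed <- function(index, img, k = 10L,
                         max_radius = index$config$max_radius) {
  if (length(index$ids) == 0L) stop("empty index")
  if (k < 1L) stop("k must be >= 1")
  q <- query_descriptor(index, img)
  qkey <- klsh_hash(index$klsh, q)
  # distance from the query key to each record's key, grouped by bucket
  dists <- as.integer(colSums(t(index$keys) != qkey))
  if (max_radius >= index$config$b) {
    # unbounded radius: the full candidate pool, identical to a linear scan
    candidates <- seq_along(index$ids)
  } else {
    target <- max(k, 3L * k)
    radius <- -1L
    candidates <- integer(0)
    while (length(candidates) < target && radius < max_radius) {
      radius <- radius + 1L
      candidates <- which(dists <= radius)
    }
  }
  if (length(candidates) == 0L)
    return(order_result(index, numeric(0), integer(0), k, "hashed", 0L))
  sims <- similarity_rows(index$descriptors[candidates, , drop = FALSE], q)
  order_result(index, sims, candidates, k, "hashed", length(candidates))
}

#' Write query results to CSV and JSON
#'
#' @param results Named list of `query_result` objects (names = query
#'   ids), or a single result with `query_id`.
#' @param path_prefix Output prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @param query_id Id used for a single unnamed result.
#' @return Written paths, invisibly.
#' @export
write_query_results <- function(results, path_prefix, query_id = "query") {
  if (inherits(results, "query_result"))
    results <- stats::setNames(list(results), query_id)
  rows <- do.call(rbind, lapply(names(results), function(qid) {
    r <- results[[qid]]$ranked
    if (nrow(r) == 0L) return(NULL)
    data.frame(query_id = qid, rank = seq_len(nrow(r)), hit_id = r$id,
               score = r$sim, stringsAsFactors = FALSE)
  }))
  csv <- paste0(path_prefix, ".csv"); js <- paste0(path_prefix, ".json")
  utils::write.csv(rows, csv, row.names = FALSE)
  jsonlite::write_json(results, js, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(c(csv, js))
}
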