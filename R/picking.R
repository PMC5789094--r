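# Grouping localizations into candidate nanoruler structures and filtering
# them. Clustering is a grid-bucketed DBSCAN written here (density-based
# grouping is the SMLM standard for structure picking).

#' Picking (structure identification) configuration
#'
#' @param radius_nm DBSCAN neighbourhood radius (nm); a good default is
#'   1.5 x the nominal intermark distance so both marks of one ruler fall in
#'   a single cluster.
#' @param min_neighbors minimum neighbours (self included) for a core point.
#' @param min_locs,max_locs accepted localization-count range per candidate.
#' @param min_rgyr_nm,max_rgyr_nm accepted radius-of-gyration range (nm).
#' @param bimodality_min minimum ratio of the first to the second principal
#'   variance; a two-mark ruler is strongly elongated, a single blob is not.
#' @param edge_margin_nm candidates whose centroid lies closer than this to
#'   the field border are rejected.
#' @return object of class `picking_config`.
#' @export
picking_config <- function(radius_nm = 90, min_neighbors = 10,
                           min_locs = 20, max_locs = 10000,
                           min_rgyr_nm = 8, max_rgyr_nm = 80,
                           bimodality_min = 3, edge_margin_nm = 200) {
  stopifnot(radius_nm > 0, min_neighbors >= 1,
            min_locs < max_locs, min_rgyr_nm < max_rgyr_nm,
            bimodality_min > 0, edge_margin_nm >= 0)
  structure(list(radius_nm = radius_nm, min_neighbors = min_neighbors,
                 min_locs = min_locs, max_locs = max_locs,
                 min_rgyr_nm = min_rgyr_nm, max_rgyr_nm = max_rgyr_nm,
                 bimodality_min = bimodality_min,
                 edge_margin_nm = edge_margin_nm),
            class = "picking_config")
}

# neighbour lists within eps via grid buckets of size eps (9-cell search)
.eps_neighbors <- function(x, y, eps) {
  n <- length(x)
  cx <- floor(x / eps)
  cy <- floor(y / eps)
  cx <- cx - min(cx)
  cy <- cy - min(cy)
  m <- max(cx) + 3
  key <- cx + m * cy
  buckets <- split(seq_len(n), key)
  bkeys <- as.numeric(names(buckets))
  offs <- c(outer(c(-1, 0, 1), c(-m, 0, m), "+"))
  nb <- vector("list", n)
  eps2 <- eps^2
  for (b in seq_along(buckets)) {
    pts <- buckets[[b]]
    cand_b <- match(bkeys[b] + offs, bkeys)
    cand <- unlist(buckets[cand_b[!is.na(cand_b)]], use.names = FALSE)
    dx <- outer(x[pts], x[cand], "-")
    dy <- outer(y[pts], y[cand], "-")
    close <- dx * dx + dy * dy <= eps2
    for (i in seq_along(pts)) nb[[pts[i]]] <- cand[close[i, ]]
  }
  nb
}

#' Cluster localizations into candidate structures (DBSCAN)
#'
#' Density-based grouping: points with at least `min_neighbors` neighbours
#' within `radius_nm` (self included) are core points; clusters are the
#' connected components of core points, and non-core points within reach of a
#' core point join the cluster of their nearest core neighbour (which makes
#' the result independent of row order). Everything else is noise.
#'
#' @param table a [localization_table()].
#' @param config a [picking_config()].
#' @return object of class `nanoruler_candidates`: list with `candidates`
#'   (data.frame `id`, `x_nm`, `y_nm`, `rgyr_nm`, `n_locs`, `accepted`,
#'   `reason`), `assignment` (integer per localization, 0 = noise) and the
#'   configuration. Candidates come out unfiltered; see
#'   [filter_candidates()].
#' @export
cluster_localizations <- function(table, config = picking_config()) {
  n <- nrow(table)
  asn <- integer(n)
  if (n > 0) {
    x <- table$x_nm
    y <- table$y_nm
    nb <- .eps_neighbors(x, y, config$radius_nm)
    deg <- lengths(nb)
    core <- deg >= config$min_neighbors
    cid <- 0L
    for (i in which(core)) {
      if (asn[i] != 0L) next
      cid <- cid + 1L
      asn[i] <- cid
      stack <- i
      while (length(stack)) {
        j <- stack[length(stack)]
        stack <- stack[-length(stack)]
        nbrs <- nb[[j]]
        newc <- nbrs[core[nbrs] & asn[nbrs] == 0L]
        if (length(newc)) {
          asn[newc] <- cid
          stack <- c(stack, newc)
        }
      }
    }
    # border points: nearest core neighbour decides (deterministic)
    for (i in which(!core)) {
      nbrs <- nb[[i]]
      cores <- nbrs[core[nbrs]]
      if (length(cores)) {
        d2 <- (x[cores] - x[i])^2 + (y[cores] - y[i])^2
        best <- cores[order(d2, asn[cores])][1]
        asn[i] <- asn[best]
      }
    }
  }
  ids <- sort(unique(asn[asn > 0L]))
  cand <- data.frame(id = ids, x_nm = rep(NA_real_, length(ids)),
                     rgyr_nm = rep(NA_real_, length(ids)),
                     n_locs = rep(NA_integer_, length(ids)),
                     accepted = rep(NA, length(ids)),
                     reason = rep("", length(ids)),
                     stringsAsFactors = FALSE)
  cand$y_nm <- rep(NA_real_, length(ids))
  cand <- cand[, c("id", "x_nm", "y_nm", "rgyr_nm", "n_locs",
                   "accepted", "reason")]
  for (r in seq_along(ids)) {
    m <- asn == ids[r]
    cand$x_nm[r] <- mean(table$x_nm[m])
    cand$y_nm[r] <- mean(table$y_nm[m])
    cand$rgyr_nm[r] <- sqrt(mean((table$x_nm[m] - cand$x_nm[r])^2 +
                                   (table$y_nm[m] - cand$y_nm[r])^2))
    cand$n_locs[r] <- sum(m)
  }
  structure(list(candidates = cand, assignment = asn, config = config,
                 field = attr(table, "field")),
            class = "nanoruler_candidates")
}

#' @export
print.nanoruler_candidates <- function(x, ...) {
  nacc <- sum(x$candidates$accepted, na.rm = TRUE)
  cat(sprintf("Nanoruler candidates: %d clusters (%d localizations assigned)\n",
              nrow(x$candidates), sum(x$assignment > 0)))
  if (!all(is.na(x$candidates$accepted)))
    cat(sprintf("  accepted after filtering: %d\n", nacc))
  invisible(x)
}

# ratio of principal variances of a 2D point cloud (>= 1)
.principal_ratio <- function(x, y) {
  if (length(x) < 3L) return(1)
  ev <- eigen(stats::cov(cbind(x, y)), symmetric = TRUE,
              only.values = TRUE)$values
  if (ev[2] <= 0) return(Inf)
  ev[1] / ev[2]
}

#' Filter candidate structures
#'
#' Applies the acceptance filters in a fixed order — localization count,
#' size (radius of gyration), bimodality (principal-variance ratio), field
#' edge — and records the first failed test as the rejection reason
#' (`too_few_locs`, `too_large`, `too_small`, `not_bimodal`, `edge`).
#'
#' @param cands a [cluster_localizations()] result.
#' @param table the localization table the candidates were derived from.
#' @param config a [picking_config()] (defaults to the one used for
#'   clustering).
#' @return `cands` with `accepted` / `reason` filled in.
#' @export
filter_candidates <- function(cands, table, config = cands$config) {
  cd <- cands$candidates
  fld <- cands$field
  if (is.null(fld)) fld <- c(max(table$x_nm, 0), max(table$y_nm, 0))
  for (r in seq_len(nrow(cd))) {
    m <- cands$assignment == cd$id[r]
    reason <- ""
    if (cd$n_locs[r] < config$min_locs) {
      reason <- "too_few_locs"
    } else if (cd$n_locs[r] > config$max_locs) {
      reason <- "too_large"
    } else if (cd$rgyr_nm[r] > config$max_rgyr_nm) {
      reason <- "too_large"
    } else if (cd$rgyr_nm[r] < config$min_rgyr_nm) {
      reason <- "too_small"
    } else if (.principal_ratio(table$x_nm[m], table$y_nm[m]) <
               config$bimodality_min) {
      reason <- "not_bimodal"
    } else if (cd$x_nm[r] < config$edge_margin_nm ||
               cd$y_nm[r] < config$edge_margin_nm ||
               cd$x_nm[r] > fld[1] - config$edge_margin_nm ||
               cd$y_nm[r] > fld[2] - config$edge_margin_nm) {
      reason <- "edge"
    }
    cd$accepted[r] <- reason == ""
    cd$reason[r] <- reason
  }
  cands$candidates <- cd
  cands
}

#' Picking-bias uncertainty from two picking configurations
#'
#' The structure-identification step can bias the ensemble mean distance
#' (automated filters pick a small subset of false structures; manual picking
#' is subjective). Running the same data through two picking configurations —
#' e.g. an "automated" and a stricter "manual-like" one — and taking the
#' absolute difference of the ensemble mean distances yields a standard
#' uncertainty surrogate for this false-positive / picking bias.
#'
#' @param table a [localization_table()].
#' @param configA,configB two [picking_config()]s.
#' @param min_structures both arms must yield at least this many accepted and
#'   successfully fitted structures.
#' @return list with `u_fp_nm` (|meanA - meanB|, nm), per-arm means and
#'   structure counts.
#' @export
estimate_fp_uncertainty <- function(table, configA, configB,
                                    min_structures = 30) {
  arm <- function(cfg) {
    cands <- filter_candidates(cluster_localizations(table, cfg), table, cfg)
    fits <- fit_candidates(table, cands)
    ensemble_stats(fits, attr(table, "pixel_size"))
  }
  ea <- arm(configA)
  eb <- arm(configB)
  if (ea$n < min_structures || eb$n < min_structures)
    stop(sprintf(paste0("too few accepted structures for picking-bias ",
                        "estimate: %d (A) and %d (B), need >= %d"),
                 ea$n, eb$n, min_structures), call. = FALSE)
  list(u_fp_nm = abs(ea$mean_nm - eb$mean_nm),
       mean_A_nm = ea$mean_nm, mean_B_nm = eb$mean_nm,
       n_A = ea$n, n_B = eb$n)
}
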