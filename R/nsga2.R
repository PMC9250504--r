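#' NSGA-II run configuration
#'
#' Defaults follow standard practice for binary channel selection: population
#' 100, 400 generations, crossover probability 0.9, mutation probability
#' 1/C (C = number of decision variables), SBX and polynomial-mutation
#' distribution indices 20.
#'
#' @param pop_size population size P (even).
#' @param generations number of generations.
#' @param pc crossover probability.
#' @param pm per-gene mutation probability; `NULL` means `1/C`.
#' @param sbx_eta simulated-binary-crossover distribution index.
#' @param mut_eta polynomial-mutation distribution index.
#' @param seed integer RNG seed for the run.
#' @param encoding `"real"` (default): SBX + polynomial mutation on real
#'   gene proxies in `[0, 1]`, thresholded at 0.5 when decoding to channel
#'   bits — the behavior of real-coded NSGA-II solvers adapted to binary
#'   chromosomes. `"binary"`: uniform crossover + bit-flip mutation directly
#'   on bits.
#' @return List of class `ga_config`.
#' @export
ga_config <- function(pop_size = 100, generations = 400, pc = 0.9, pm = NULL,
                      sbx_eta = 20, mut_eta = 20, seed = 1,
                      encoding = c("real", "binary")) {
  encoding <- match.arg(encoding)
  if (pop_size < 2 || pop_size %% 2 != 0)
    stop("pop_size must be an even number >= 2", call. = FALSE)
  if (pc < 0 || pc > 1 || (!is.null(pm) && (pm < 0 || pm > 1)))
    stop("pc and pm must be probabilities", call. = FALSE)
  structure(list(pop_size = pop_size, generations = generations, pc = pc,
                 pm = pm, sbx_eta = sbx_eta, mut_eta = mut_eta, seed = seed,
                 encoding = encoding), class = "ga_config")
}

#' Pareto dominance (minimization)
#'
#' `a` dominates `b` iff `a <= b` in every objective and `a < b` in at least
#' one.
#'
#' @param a,b equal-length objective vectors (all minimized).
#' @return Logical.
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b))
    stop_mismatch("objective length", length(b), length(a))
  all(a <= b) && any(a < b)
}

# P x P logical matrix; [i, j] TRUE iff individual i dominates j.
domination_matrix <- function(obj) {
  P <- nrow(obj)
  le <- matrix(TRUE, P, P)
  lt <- matrix(FALSE, P, P)
  for (k in seq_len(ncol(obj))) {
    le <- le & outer(obj[, k], obj[, k], "<=")
    lt <- lt | outer(obj[, k], obj[, k], "<")
  }
  le & lt
}

#' Fast non-dominated sorting
#'
#' Partitions a population into Pareto fronts: front 1 is the non-dominated
#' set; front k+1 is non-dominated once fronts <= k are removed.
#'
#' @param objectives P x O matrix of objective values (minimization), or a
#'   list of equal-length objective vectors.
#' @return List of integer index vectors, one per front.
#' @export
nondominated_sort <- function(objectives) {
  if (is.list(objectives)) objectives <- do.call(rbind, objectives)
  objectives <- as.matrix(objectives)
  P <- nrow(objectives)
  if (P == 0) stop("empty population", call. = FALSE)
  dom <- domination_matrix(objectives)
  n_dom <- colSums(dom)          # how many dominate j
  fronts <- list()
  assigned <- rep(FALSE, P)
  while (!all(assigned)) {
    cur <- which(!assigned & n_dom == 0)
    if (length(cur) == 0) stop("non-dominated sort failed", call. = FALSE)
    fronts[[length(fronts) + 1]] <- cur
    assigned[cur] <- TRUE
    if (length(cur) == 1) {
      n_dom <- n_dom - dom[cur, ]
    } else {
      n_dom <- n_dom - colSums(dom[cur, , drop = FALSE])
    }
    n_dom[assigned] <- -1L
  }
  fronts
}

#' Crowding distance within a front
#'
#' Per objective, boundary individuals get `Inf`; interior individuals
#' accumulate the normalized gap between their neighbors in the sorted
#' order. Objectives with zero range contribute nothing.
#'
#' @param front_objectives F x O objective matrix for one front.
#' @return Numeric vector of length F.
#' @export
crowding_distance <- function(front_objectives) {
  front_objectives <- as.matrix(front_objectives)
  F_ <- nrow(front_objectives)
  if (F_ == 0) stop("empty front", call. = FALSE)
  if (F_ <= 2) return(rep(Inf, F_))
  dist <- numeric(F_)
  for (k in seq_len(ncol(front_objectives))) {
    v <- front_objectives[, k]
    ord <- order(v)
    rng <- v[ord[F_]] - v[ord[1]]
    dist[ord[c(1, F_)]] <- Inf
    if (rng > 0) {
      interior <- ord[2:(F_ - 1)]
      dist[interior] <- dist[interior] +
        (v[ord[3:F_]] - v[ord[1:(F_ - 2)]]) / rng
    }
  }
  dist
}

# rank + crowding for a whole population; returns list(rank, crowding).
rank_population <- function(obj) {
  fronts <- nondominated_sort(obj)
  rank <- integer(nrow(obj))
  crowd <- numeric(nrow(obj))
  for (f in seq_along(fronts)) {
    idx <- fronts[[f]]
    rank[idx] <- f
    crowd[idx] <- crowding_distance(obj[idx, , drop = FALSE])
  }
  list(rank = rank, crowding = crowd, fronts = fronts)
}

# Binary tournament on (rank asc, crowding desc); returns n winner indices.
tournament_select <- function(rank, crowding, n) {
  P <- length(rank)
  i <- sample.int(P, n, replace = TRUE)
  j <- sample.int(P, n, replace = TRUE)
  pick_j <- (rank[j] < rank[i]) |
    (rank[j] == rank[i] & crowding[j] > crowding[i])
  ifelse(pick_j, j, i)
}

# Simulated binary crossover on one pair of [0,1] gene-proxy vectors.
sbx_pair <- function(p1, p2, eta) {
  C <- length(p1)
  u <- stats::runif(C)
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta + 1)))
  do_x <- stats::runif(C) < 0.5
  beta[!do_x] <- 1
  c1 <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
  c2 <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
  list(pmin(1, pmax(0, c1)), pmin(1, pmax(0, c2)))
}

# Polynomial mutation, per gene with probability pm, on a matrix of proxies.
poly_mutate <- function(X, pm, eta) {
  hit <- matrix(stats::runif(length(X)) < pm, nrow(X), ncol(X))
  if (!any(hit)) return(X)
  u <- stats::runif(sum(hit))
  delta <- ifelse(u < 0.5, (2 * u)^(1 / (eta + 1)) - 1,
                  1 - (2 * (1 - u))^(1 / (eta + 1)))
  X[hit] <- pmin(1, pmax(0, X[hit] + delta))
  X
}

#' Create an offspring population
#'
#' Binary tournament by (rank, crowding), then for the real encoding SBX
#' with probability `pc` and polynomial mutation with per-gene probability
#' `pm` on the `[0, 1]` gene proxies; for the binary encoding uniform
#' crossover and bit-flip mutation. Genes outside the montage mask are
#' re-clamped to 0.
#'
#' @param proxies P x C matrix of parent gene proxies.
#' @param rank,crowding parent ranking from non-dominated sorting.
#' @param config a [ga_config()].
#' @param mask logical vector of allowed genes (length C).
#' @return P x C matrix of offspring proxies.
#' @export
make_offspring <- function(proxies, rank, crowding, config, mask = NULL) {
  P <- nrow(proxies); C <- ncol(proxies)
  pm <- if (is.null(config$pm)) 1 / C else config$pm
  parents <- tournament_select(rank, crowding, P)
  kids <- matrix(0, P, C)
  for (p in seq_len(P / 2)) {
    i1 <- parents[2 * p - 1]; i2 <- parents[2 * p]
    k1 <- proxies[i1, ]; k2 <- proxies[i2, ]
    if (stats::runif(1) < config$pc) {
      if (config$encoding == "real") {
        kk <- sbx_pair(k1, k2, config$sbx_eta)
        k1 <- kk[[1]]; k2 <- kk[[2]]
      } else {
        sw <- stats::runif(C) < 0.5
        tmp <- k1[sw]; k1[sw] <- k2[sw]; k2[sw] <- tmp
      }
    }
    kids[2 * p - 1, ] <- k1
    kids[2 * p, ] <- k2
  }
  kids <- if (config$encoding == "real") {
    poly_mutate(kids, pm, config$mut_eta)
  } else {
    flip <- matrix(stats::runif(length(kids)) < pm, P, C)
    abs(kids - flip)
  }
  if (!is.null(mask)) kids[, !mask] <- 0
  kids
}

decode_bits <- function(proxies, mask = NULL) {
  bits <- proxies >= 0.5
  if (!is.null(mask)) bits[, !mask] <- FALSE
  bits
}

#' Run the elitist multi-objective genetic algorithm
#'
#' Evolves binary channel chromosomes against a user-supplied objective
#' function: P random masked chromosomes are initialized and evaluated
#' (logged as generation 0); each generation creates P offspring, evaluates
#' them, merges the 2P individuals and truncates back to P by non-dominated
#' sorting with crowding-distance ties. Every evaluated (chromosome,
#' objectives) pair is logged. Objective evaluations are cached on the
#' decoded bitstring, since duplicate chromosomes recur; cached offspring
#' are still logged, so a run of P x G generations always logs exactly
#' P * G offspring rows.
#'
#' @param evaluate function taking a logical gene vector and returning a
#'   numeric objective vector (all minimized); must be deterministic within
#'   a run.
#' @param n_genes chromosome length C.
#' @param config a [ga_config()].
#' @param mask optional logical montage mask of length C; genes outside it
#'   are clamped to 0 in every individual.
#' @return List of class `candidate_log`: `log` data.frame (generation,
#'   bitstring, n_channels, obj_1..obj_O), `final_proxies`, `final_obj`,
#'   `pop_min` (per-generation population minima, one row per generation
#'   including generation 0), `config`, `n_genes`, `mask`.
#' @export
evolve <- function(evaluate, n_genes, config = ga_config(), mask = NULL) {
  if (!is.null(mask) && length(mask) != n_genes)
    stop_mismatch("mask length", length(mask), n_genes)
  P <- config$pop_size
  cache <- new.env(parent = emptyenv())
  eval_bits <- function(bits_mat) {
    rows <- lapply(seq_len(nrow(bits_mat)), function(r) {
      b <- bits_mat[r, ]
      key <- bits_to_string(b)
      val <- cache[[key]]
      if (is.null(val)) {
        val <- tryCatch(evaluate(b), error = function(e)
          stop(sprintf("objective evaluation failed for chromosome %s: %s",
                       key, conditionMessage(e)), call. = FALSE))
        cache[[key]] <- val
      }
      val
    })
    do.call(rbind, rows)
  }
  local_seed(config$seed, {
    proxies <- matrix(stats::runif(P * n_genes), P, n_genes)
    if (!is.null(mask)) proxies[, !mask] <- 0
    bits <- decode_bits(proxies, mask)
    obj <- eval_bits(bits)
    gen_log <- vector("list", config$generations + 1L)
    gen_log[[1]] <- list(gen = rep(0L, P),
                         key = apply(bits, 1, bits_to_string), obj = obj)
    rk <- rank_population(obj)
    pop_min <- matrix(NA_real_, config$generations + 1L, ncol(obj))
    pop_min[1L, ] <- apply(obj, 2, min)
    for (g in seq_len(config$generations)) {
      kids <- make_offspring(proxies, rk$rank, rk$crowding, config, mask)
      kid_bits <- decode_bits(kids, mask)
      kid_obj <- eval_bits(kid_bits)
      gen_log[[g + 1L]] <- list(gen = rep(g, P),
                                key = apply(kid_bits, 1, bits_to_string),
                                obj = kid_obj)
      merged <- rbind(proxies, kids)
      merged_obj <- rbind(obj, kid_obj)
      rk_m <- rank_population(merged_obj)
      keep <- integer(0)
      for (f in seq_along(rk_m$fronts)) {
        idx <- rk_m$fronts[[f]]
        if (length(keep) + length(idx) <= P) {
          keep <- c(keep, idx)
        } else {
          slots <- P - length(keep)
          ord <- idx[order(rk_m$crowding[idx], decreasing = TRUE)]
          keep <- c(keep, ord[seq_len(slots)])
          break
        }
      }
      proxies <- merged[keep, , drop = FALSE]
      obj <- merged_obj[keep, , drop = FALSE]
      rk <- rank_population(obj)
      pop_min[g + 1L, ] <- apply(obj, 2, min)
    }
  })
  gens <- unlist(lapply(gen_log, `[[`, "gen"))
  keys <- unlist(lapply(gen_log, `[[`, "key"))
  objs <- do.call(rbind, lapply(gen_log, `[[`, "obj"))
  colnames(objs) <- paste0("obj_", seq_len(ncol(objs)))
  log <- data.frame(generation = gens, bitstring = keys,
                    n_channels = vapply(keys, function(k)
                      sum(string_to_bits(k)), integer(1), USE.NAMES = FALSE),
                    stringsAsFactors = FALSE)
  log <- cbind(log, as.data.frame(objs))
  structure(list(log = log, final_proxies = proxies, final_obj = obj,
                 pop_min = pop_min, config = config, n_genes = n_genes,
                 mask = mask),
            class = "candidate_log")
}

#' @export
print.candidate_log <- function(x, ...) {
  cat(sprintf("<candidate_log> %d evaluations (%d offspring), %d genes, %d objectives\n",
              nrow(x$log), sum(x$log$generation > 0), x$n_genes,
              sum(startsWith(names(x$log), "obj_"))))
  invisible(x)
}

#' Write a candidate log as delimited text
#'
#' One row per evaluated candidate: generation, chromosome bitstring,
#' channel count and objective values. A header comment records the seed.
#'
#' @param candidate_log an [evolve()] result.
#' @param file output path.
#' @export
write_candidate_log <- function(candidate_log, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# eegselect candidate log; seed=%d; genes=%d",
                     candidate_log$config$seed, candidate_log$n_genes), con)
  utils::write.table(candidate_log$log, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}
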