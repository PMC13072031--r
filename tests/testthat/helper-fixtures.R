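# Fixtures are built in code: small deterministic tables at the published
# group means, plus random valid datasets for property-style tests.

published_needle_means <- function() {
  tibble::tribble(
    ~condition, ~position, ~c_mg_g, ~n_mg_g, ~p_mg_g,
    "healthy", "apical", 447.8, 21.9, 8.3,
    "healthy", "basal", 481.8, 12.8, 4.3,
    "chlorotic", "apical", 461.4, 24.7, 7.9,
    "chlorotic", "basal", 472.4, 7.2, 1.6)
}

# 4 groups x 3 trees, every tree exactly at its group mean
constant_needle_fixture <- function(n_trees = 3) {
  means <- published_needle_means()
  purrr::pmap(means, function(condition, position, c_mg_g, n_mg_g, p_mg_g) {
    prefix <- if (condition == "healthy") "H" else "C"
    tibble::tibble(
      sample_id = paste0(prefix, seq_len(n_trees), "-", substr(position, 1, 3)),
      tree_id = paste0(prefix, seq_len(n_trees)),
      condition = condition, position = position,
      c_mg_g = c_mg_g, n_mg_g = n_mg_g, p_mg_g = p_mg_g)
  }) |> dplyr::bind_rows()
}

constant_soil_fixture <- function(n_trees = 3, c = 2.30, n = 0.23, p = 0.13) {
  grid <- tidyr::expand_grid(
    condition = c("healthy", "chlorotic"),
    tree = seq_len(n_trees),
    soil_layer = c("0-20", "20-40", "40-60", "60-80", "80-100"))
  grid |>
    dplyr::mutate(tree_id = paste0(ifelse(condition == "healthy", "H", "C"), tree),
                  sample_id = paste0(tree_id, "-s", soil_layer),
                  c_mg_g = c, n_mg_g = n, p_mg_g = p) |>
    dplyr::select(sample_id, tree_id, condition, soil_layer, c_mg_g, n_mg_g, p_mg_g)
}

random_valid_needles <- function(n_trees = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- tidyr::expand_grid(condition = c("healthy", "chlorotic"),
                             tree = seq_len(n_trees),
                             position = c("apical", "basal"))
  grid |>
    dplyr::mutate(tree_id = paste0(ifelse(condition == "healthy", "H", "C"), tree),
                  sample_id = paste0(tree_id, "-", substr(position, 1, 3)),
                  c_mg_g = runif(dplyr::n(), 300, 600),
                  n_mg_g = runif(dplyr::n(), 2, 40),
                  p_mg_g = runif(dplyr::n(), 0.5, 12)) |>
    dplyr::select(sample_id, tree_id, condition, position,
                  c_mg_g, n_mg_g, p_mg_g)
}

random_valid_soils <- function(n_trees = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  constant_soil_fixture(n_trees) |>
    dplyr::mutate(c_mg_g = runif(dplyr::n(), 1, 5),
                  n_mg_g = runif(dplyr::n(), 0.1, 0.5),
                  p_mg_g = runif(dplyr::n(), 0.05, 0.3))
}

# random symmetric pairwise p-value matrix over k groups
random_p_matrix <- function(k) {
  m <- matrix(1, k, k, dimnames = list(LETTERS[1:k], LETTERS[1:k]))
  ps <- runif(k * (k - 1) / 2)
  m[upper.tri(m)] <- ps
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# Independent compact-letter-display oracle: minimum edge-clique cover of the
# non-significance graph via igraph maximal cliques + brute-force set cover.
cld_oracle_min_letters <- function(p_mat, alpha) {
  k <- nrow(p_mat)
  adj <- p_mat >= alpha
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cliques <- lapply(igraph::max_cliques(g), as.integer)
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  covered <- function(subset) {
    ok_edges <- !nrow(edges) || all(apply(edges, 1, function(e)
      any(vapply(subset, function(cl) all(e %in% cl), logical(1)))))
    ok_edges && all(seq_len(k) %in% unlist(subset))
  }
  for (size in seq_along(cliques)) {
    for (cb in utils::combn(length(cliques), size, simplify = FALSE)) {
      if (covered(cliques[cb])) return(size)
    }
  }
  length(cliques)
}

# contract: two groups share a letter iff their comparison is non-significant
cld_contract_holds <- function(letters_tbl, p_mat, alpha) {
  k <- nrow(p_mat)
  lets <- strsplit(letters_tbl$letters[match(rownames(p_mat), letters_tbl$group)], "")
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      share <- length(intersect(lets[[i]], lets[[j]])) > 0
      if (share != (p_mat[i, j] >= alpha)) return(FALSE)
    }
  }
  all(lengths(lets) > 0)
}
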