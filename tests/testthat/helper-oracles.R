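# Independent brute-force oracles used to cross-check the vectorised
# implementations. These work straight off a raw edge tibble with plain
# loops and literal threshold comparisons.

# a random edge table on <= n neurons, returned with its connectome
random_connectome <- function(n = 30, n_edges = 120, seed = 1) {
  set.seed(seed)
  pre <- sample.int(n, n_edges, replace = TRUE)
  post <- sample.int(n, n_edges, replace = TRUE)
  keep <- pre != post
  edges <- tibble::tibble(
    pre = pre[keep], post = post[keep],
    roi = sample(c("A", "B", "C"), sum(keep), replace = TRUE),
    weight = sample(1:20, sum(keep), replace = TRUE)
  )
  edges <- edges[!duplicated(edges[, c("pre", "post")]), ]
  catalog <- tibble::tibble(
    body_id = as.numeric(seq_len(n)),
    type_label = "", sequential_label = paste0("n", seq_len(n)),
    clock_class = factor("non-clock",
                         levels = clocknet:::clock_class_levels),
    functional_group = factor("none",
                              levels = clocknet:::functional_group_levels),
    is_fragment = FALSE
  )
  list(edges = edges, x = connectome(edges, catalog = catalog))
}

# literal-threshold class check, independent of classify_strength()
brute_reaches <- function(w, min_class) {
  switch(min_class,
    weak = w >= 1,
    medium = w >= 3,
    strong = w >= 10
  )
}

brute_partner_set <- function(edges, cell, direction, min_class) {
  out <- numeric()
  for (i in seq_len(nrow(edges))) {
    if (!brute_reaches(edges$weight[i], min_class)) next
    if (direction == "outputs" && edges$pre[i] == cell) {
      out <- c(out, edges$post[i])
    }
    if (direction == "inputs" && edges$post[i] == cell) {
      out <- c(out, edges$pre[i])
    }
  }
  sort(unique(out))
}

brute_jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  inter <- 0
  for (v in a) if (any(b == v)) inter <- inter + 1
  uni <- length(a) + length(b) - inter
  if (uni == 0) 0 else inter / uni
}

brute_shared_partners <- function(edges, members, min_members) {
  sets <- lapply(members, brute_partner_set, edges = edges,
                 direction = "outputs", min_class = "strong")
  tab <- table(unlist(sets))
  sort(as.numeric(names(tab)[tab >= min_members]))
}
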