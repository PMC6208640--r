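# Shared fixtures and independent oracles. Expensive objects are built once
# per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# ---- hand-built trees with known class counts ------------------------------
# Tree A: root (2 neg, 2 pos), splits on f1; f1=0 -> (2,0), f1=1 -> (0,2).
# Tree B: root (3,1), splits on f2; f2=1 -> (2,0) leaf;
#         f2=0 -> (1,1), splits on f1; f1=0 -> (1,0), f1=1 -> (0,1).
hand_tree_a <- function() {
  structure(list(split = c(1L, NA, NA), left = c(2L, NA, NA),
                 right = c(3L, NA, NA), n_neg = c(2L, 2L, 0L),
                 n_pos = c(2L, 0L, 2L)),
            class = "decision_tree")
}

hand_tree_b <- function() {
  structure(list(split = c(2L, 1L, NA, NA, NA),
                 left = c(2L, 4L, NA, NA, NA),
                 right = c(3L, 5L, NA, NA, NA),
                 n_neg = c(3L, 1L, 2L, 1L, 0L),
                 n_pos = c(1L, 1L, 0L, 0L, 1L)),
            class = "decision_tree")
}

# a two-tree forest over features f1, f2 in which every sample is OOB
hand_forest <- function() {
  structure(list(trees = list(hand_tree_a(), hand_tree_b()),
                 ntree = 2L, mtry = 1L, min_node = 1L, seed = 1L,
                 feature_names = c("f1", "f2"),
                 class_names = c(negative = "neg", positive = "pos"),
                 n_train = 4L, inbag = matrix(0L, 4L, 2L)),
            class = "pair_forest")
}

# ---- independent oracles ---------------------------------------------------

# brute-force concordant-pair (Mann-Whitney) AUC, ties counted half
brute_auc <- function(scores, y01) {
  pos <- scores[y01 == 1]
  neg <- scores[y01 == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# independent root-to-leaf replay over a model's raw tree arrays: mean leaf
# positive fraction over the given trees (never calls package path code)
replay_leaf_fraction <- function(model, x, counted) {
  leaf <- vapply(counted, function(t) {
    tr <- model$trees[[t]]
    node <- 1L
    while (!is.na(tr$split[node])) {
      node <- if (x[tr$split[node]] == 1L) tr$right[node] else tr$left[node]
    }
    tr$n_pos[node] / (tr$n_pos[node] + tr$n_neg[node])
  }, numeric(1))
  mean(leaf)
}

# linearly separable data: label decided by feature 1 alone
separable_data <- function(n, p = 4L, seed = 1L) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 1L, 0.5), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  list(x = X, y = factor(ifelse(X[, 1L] == 1L, "pos", "neg"),
                         levels = c("neg", "pos")))
}

# label = feature 1 with a fixed flip rate (for library equivalence checks)
noisy_data <- function(n, p = 10L, flip = 0.1, seed = 1L) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 1L, 0.5), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- X[, 1L]
  fl <- runif(n) < flip
  y[fl] <- 1L - y[fl]
  list(x = X, y = factor(ifelse(y == 1L, "pos", "neg"),
                         levels = c("neg", "pos")))
}

# ---- shared synthetic community (the scaled-down mechanism-recovery run) ---
comm20 <- function() {
  cached("comm20", {
    gen <- generate_community(n_organisms = 20L, n_metabolites = 50L,
                              scenario = "single_competition", seed = 1L,
                              group_size = 4L)
    camp <- pairwise_campaign(gen$models, gen$env)
    traits <- traits_from_models(gen$models, gen$metabolites)
    dataset <- assemble_dataset(traits, camp$table, label_rule("sign"))
    model <- train_forest(dataset, ntree = 500L, seed = 1L)
    truths <- truth_list(camp$mechanisms, type = "competition")
    single <- truths[vapply(truths, length, integer(1)) == 1L]
    eligible <- intersect(names(single),
                          rownames(dataset$design)[dataset$labels == "negative"])
    list(gen = gen, camp = camp, traits = traits, dataset = dataset,
         model = model, truths = truths, single = single,
         eligible = eligible,
         cmap = candidate_map_competition(gen$metabolites))
  })
}
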