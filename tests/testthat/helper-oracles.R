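# Independent oracles and tiny fixtures used across the suite.

# LP oracle: pracma's simplex on the shifted problem (x = v - lb >= 0).
# Completely independent implementation path from the package solver.
oracle_lp <- function(A, b, lb, ub, obj, maximize = TRUE) {
  n <- length(obj)
  res <- tryCatch(
    pracma::linprog(obj, A = diag(n), b = ub - lb, Aeq = A,
                    beq = as.numeric(b - A %*% lb),
                    maximize = maximize, maxiter = 5000),
    error = function(e) NULL
  )
  if (is.null(res) || res$errno != 1) return(NULL)
  sum(obj * (res$x[1:n] + lb))
}

# Random small metabolic-style network: m internal metabolites, a feed
# exchange, a drain exchange, and random internal conversions. Guaranteed
# to contain at least one feasible path.
random_network <- function(seed, n_mets = 6, n_internal = 12) {
  set.seed(seed)
  mets <- tibble::tibble(
    id = paste0("m", seq_len(n_mets), "[c]"),
    name = paste0("met", seq_len(n_mets)),
    compartment = "c", formula = NA_character_, charge = NA_integer_
  )
  rxns <- list(
    tibble::tibble(id = "EX_in", stoich = list(c(`m1[c]` = 1)),
                   lower_bound = 0, upper_bound = 10, subsystem = "",
                   gpr = "", is_exchange = TRUE, is_sink = FALSE),
    tibble::tibble(id = "EX_out", stoich = list(stats::setNames(-1, paste0("m", n_mets, "[c]"))),
                   lower_bound = 0, upper_bound = 1000, subsystem = "",
                   gpr = "", is_exchange = TRUE, is_sink = FALSE)
  )
  # a guaranteed chain m1 -> m2 -> ... -> mk
  for (i in seq_len(n_mets - 1)) {
    st <- stats::setNames(c(-1, 1), c(paste0("m", i, "[c]"), paste0("m", i + 1, "[c]")))
    rxns[[length(rxns) + 1]] <- tibble::tibble(
      id = paste0("chain", i), stoich = list(st),
      lower_bound = 0, upper_bound = 1000, subsystem = "", gpr = "",
      is_exchange = FALSE, is_sink = FALSE)
  }
  for (j in seq_len(max(0, n_internal - (n_mets - 1)))) {
    pair <- sample(n_mets, 2)
    coef <- sample(1:2, 2, replace = TRUE)
    st <- stats::setNames(c(-coef[1], coef[2]),
                          paste0("m", pair, "[c]"))
    rev <- stats::runif(1) < 0.4
    rxns[[length(rxns) + 1]] <- tibble::tibble(
      id = paste0("r", j), stoich = list(st),
      lower_bound = if (rev) -1000 else 0, upper_bound = 1000,
      subsystem = "", gpr = "", is_exchange = FALSE, is_sink = FALSE)
  }
  metabolic_model(metabolites = mets, reactions = dplyr::bind_rows(rxns),
                  genes = character(), objective_id = "EX_out")
}

# Per-reaction brute-force FVA: for every reaction an independent pair of
# cold LPs on a freshly assembled system with the fraction-of-optimum row.
brute_fva <- function(model, fraction = 0.99) {
  p <- cblflux:::lp_parts(model)
  oi <- match(model$objective_id, model$reactions$id)
  obj <- rep(0, ncol(p$A)); obj[oi] <- 1
  top <- cblflux:::.cpp_lp_solve(p$A, p$b, p$lb, p$ub, obj, TRUE)
  stopifnot(top$status == 0L)
  A2 <- rbind(p$A, obj)
  lb2 <- p$lb; ub2 <- p$ub
  n <- ncol(p$A)
  # encode c'v >= f*opt as an extra row with slack
  A2 <- cbind(A2, c(rep(0, nrow(p$A)), -1))
  b2 <- c(p$b, 0)
  lb2 <- c(lb2, fraction * top$objective)
  ub2 <- c(ub2, 1e9)
  mn <- mx <- numeric(n)
  for (j in seq_len(n)) {
    cj <- rep(0, n + 1); cj[j] <- 1
    lo <- cblflux:::.cpp_lp_solve(A2, b2, lb2, ub2, cj, FALSE)
    hi <- cblflux:::.cpp_lp_solve(A2, b2, lb2, ub2, cj, TRUE)
    mn[j] <- lo$objective; mx[j] <- hi$objective
  }
  tibble::tibble(reaction_id = model$reactions$id, min_flux = mn, max_flux = mx)
}

# Truth-table GPR oracle: translate the rule text into an R logical
# expression and evaluate it directly.
oracle_gpr <- function(text, genes, deleted) {
  if (!nzchar(text)) return(TRUE)
  expr <- gsub("\\band\\b", "&", text, ignore.case = TRUE)
  expr <- gsub("\\bor\\b", "|", expr, ignore.case = TRUE)
  env <- new.env()
  for (g in genes) assign(g, !(g %in% deleted), envir = env)
  isTRUE(eval(parse(text = expr), envir = env))
}

random_gpr <- function(genes, depth = 2) {
  if (depth == 0 || (length(genes) == 1) || stats::runif(1) < 0.3) {
    return(sample(genes, 1))
  }
  op <- sample(c("and", "or"), 1)
  left <- random_gpr(genes, depth - 1)
  right <- random_gpr(genes, depth - 1)
  paste0("(", left, " ", op, " ", right, ")")
}

# Exact two-sided rank-sum p by enumeration over all label assignments.
enumerate_ranksum_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(pool); na <- length(a)
  r <- rank(pool)
  obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2  # Mann-Whitney U of a
  combs <- utils::combn(n, na)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(us <= obs), mean(us >= obs)))
}

# Direct Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Naive complete-linkage agglomeration returning merge heights in order.
naive_complete_linkage <- function(x) {
  d <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        dd <- max(d[clusters[[i]], clusters[[j]]])
        if (dd < bestd - 1e-12) { bestd <- dd; best <- c(j, i) }
      }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Small hand-built models -----------------------------------------------------

# EX_a (uptake <= cap) -> a -> b -> EX_b
make_chain_model <- function(cap = 10) {
  mets <- tibble::tibble(id = c("a[c]", "b[c]"), name = c("a", "b"),
                         compartment = "c", formula = NA_character_,
                         charge = NA_integer_)
  rxns <- dplyr::bind_rows(
    tibble::tibble(id = "EX_a", stoich = list(c(`a[c]` = 1)),
                   lower_bound = 0, upper_bound = cap, subsystem = "",
                   gpr = "", is_exchange = TRUE, is_sink = FALSE),
    tibble::tibble(id = "AB", stoich = list(c(`a[c]` = -1, `b[c]` = 1)),
                   lower_bound = 0, upper_bound = 1000, subsystem = "",
                   gpr = "", is_exchange = FALSE, is_sink = FALSE),
    tibble::tibble(id = "EX_b", stoich = list(c(`b[c]` = -1)),
                   lower_bound = 0, upper_bound = 1000, subsystem = "",
                   gpr = "", is_exchange = TRUE, is_sink = FALSE)
  )
  metabolic_model(metabolites = mets, reactions = rxns, genes = character(),
                  objective_id = "EX_b")
}

# Two parallel branches of capacity `cap` each feeding a demand.
make_branch_model <- function(cap = 10) {
  mets <- tibble::tibble(id = c("a[c]", "b[c]"), name = c("a", "b"),
                         compartment = "c", formula = NA_character_,
                         charge = NA_integer_)
  rxns <- dplyr::bind_rows(
    tibble::tibble(id = "EX_a", stoich = list(c(`a[c]` = 1)),
                   lower_bound = 0, upper_bound = cap, subsystem = "",
                   gpr = "", is_exchange = TRUE, is_sink = FALSE),
    tibble::tibble(id = "branch1", stoich = list(c(`a[c]` = -1, `b[c]` = 1)),
                   lower_bound = 0, upper_bound = cap, subsystem = "",
                   gpr = "", is_exchange = FALSE, is_sink = FALSE),
    tibble::tibble(id = "branch2", stoich = list(c(`a[c]` = -1, `b[c]` = 1)),
                   lower_bound = 0, upper_bound = cap, subsystem = "",
                   gpr = "", is_exchange = FALSE, is_sink = FALSE),
    tibble::tibble(id = "EX_b", stoich = list(c(`b[c]` = -1)),
                   lower_bound = 0, upper_bound = 1000, subsystem = "",
                   gpr = "", is_exchange = TRUE, is_sink = FALSE)
  )
  metabolic_model(metabolites = mets, reactions = rxns, genes = character(),
                  objective_id = "EX_b")
}

# Shared fixture objects (built once per test run)
fixture_model_cached <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- build_fixture_model()
    val
  }
})

battery_cached <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- run_scenario_battery(fixture_model_cached())
    val
  }
})
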