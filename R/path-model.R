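#' Declarative path models in the reticular-action (RAM) formulation
#'
#' A `path_model` holds three sparse sets of entries over a node set: directed
#' path coefficients (the asymmetric matrix `A`, with `A[to, from]` the
#' coefficient of `from` in the equation for `to`), symmetric (co)variances of
#' the node disturbances (`S`), and node intercepts (`M`). Each entry is either
#' fixed at a numeric value or free, carrying a character label; re-using a
#' label across entries imposes an equality constraint. Observed nodes are
#' selected by a filter matrix, so implied moments over the observed variables
#' follow from the usual total-effects identity (see [implied_moments()]).
#'
#' @param observed character vector of observed node names (the selection
#'   order used for implied moments and data alignment).
#' @param latent character vector of latent node names.
#' @return An object of class `path_model`.
#' @seealso [add_path()], [add_cov()], [add_mean()], [implied_moments()],
#'   [model_df()], [fit_ml()]
#' @examples
#' m <- path_model(observed = c("x", "y"))
#' m <- add_path(m, "x", "y", label = "b")
#' m <- add_cov(m, "x", "x", label = "vx")
#' m <- add_cov(m, "y", "y", label = "vy")
#' m <- add_mean(m, "x", label = "mx")
#' m <- add_mean(m, "y", label = "my")
#' model_df(m)
#' @export
path_model <- function(observed, latent = character()) {
  stopifnot(is.character(observed), length(observed) > 0)
  stopifnot(is.character(latent))
  nodes <- c(observed, latent)
  if (anyDuplicated(nodes)) {
    stop("duplicated node names: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  }
  structure(
    list(
      observed = observed,
      latent = latent,
      paths = empty_entries(c("from", "to")),
      covs = empty_entries(c("node1", "node2")),
      means = empty_entries("node")
    ),
    class = "path_model"
  )
}

empty_entries <- function(cols) {
  out <- stats::setNames(rep(list(character()), length(cols)), cols)
  out$value <- numeric()
  out$label <- character()
  as.data.frame(out, stringsAsFactors = FALSE)
}

model_nodes <- function(model) c(model$observed, model$latent)

check_node <- function(model, node, arg) {
  if (!node %in% model_nodes(model)) {
    stop(sprintf("unknown node `%s` (argument %s)", node, arg), call. = FALSE)
  }
}

entry_label <- function(label) {
  if (is.null(label) || length(label) == 0 || is.na(label[1])) {
    NA_character_
  } else {
    as.character(label[1])
  }
}

#' Add a directed path to a path model
#'
#' @param model a [path_model()].
#' @param from,to node names; the coefficient multiplies `from` in the
#'   structural equation of `to`.
#' @param value fixed value (when `label` is `NA`) or start value hint.
#' @param label `NA` for a fixed entry, otherwise the free-parameter label.
#' @return The modified model.
#' @export
add_path <- function(model, from, to, value = 0, label = NA) {
  check_node(model, from, "from"); check_node(model, to, "to")
  if (from == to) stop("self-loop paths are not allowed")
  dup <- model$paths$from == from & model$paths$to == to
  if (any(dup)) stop(sprintf("path %s -> %s already present", from, to))
  model$paths[nrow(model$paths) + 1L, ] <-
    list(from, to, as.numeric(value), entry_label(label))
  model
}

#' Add a (co)variance entry to a path model
#'
#' `node1 == node2` gives a disturbance variance; otherwise a disturbance
#' covariance. Entries are stored unordered (the pair is normalised).
#'
#' @inheritParams add_path
#' @param node1,node2 node names.
#' @return The modified model.
#' @export
add_cov <- function(model, node1, node2, value = 0, label = NA) {
  check_node(model, node1, "node1"); check_node(model, node2, "node2")
  pair <- sort(c(node1, node2))
  dup <- model$covs$node1 == pair[1] & model$covs$node2 == pair[2]
  if (any(dup)) stop(sprintf("covariance entry %s ~~ %s already present",
                             pair[1], pair[2]))
  model$covs[nrow(model$covs) + 1L, ] <-
    list(pair[1], pair[2], as.numeric(value), entry_label(label))
  model
}

#' Add an intercept entry to a path model
#'
#' @inheritParams add_path
#' @param node node name.
#' @return The modified model.
#' @export
add_mean <- function(model, node, value = 0, label = NA) {
  check_node(model, node, "node")
  if (any(model$means$node == node)) {
    stop(sprintf("mean entry for %s already present", node))
  }
  model$means[nrow(model$means) + 1L, ] <-
    list(node, as.numeric(value), entry_label(label))
  model
}

#' Free parameter labels of a path model
#'
#' @param model a [path_model()].
#' @return Character vector of distinct labels, in first-appearance order
#'   (paths, then covariances, then means).
#' @export
free_labels <- function(model) {
  labs <- c(model$paths$label, model$covs$label, model$means$label)
  unique(labs[!is.na(labs)])
}

# Kahn topological sort over the directed-path edges; errors on a cycle.
validate_path_model <- function(model) {
  nodes <- model_nodes(model)
  if (nrow(model$paths) > 0) {
    indeg <- stats::setNames(integer(length(nodes)), nodes)
    edges <- split(model$paths$to, model$paths$from)
    for (to in model$paths$to) indeg[to] <- indeg[to] + 1L
    queue <- nodes[indeg == 0L]
    seen <- 0L
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
      for (to in edges[[v]] %||% character()) {
        indeg[to] <- indeg[to] - 1L
        if (indeg[to] == 0L) queue <- c(queue, to)
      }
    }
    if (seen < length(nodes)) {
      stop("directed paths contain a cycle; only recursive models are supported")
    }
  }
  invisible(model)
}

#' Model degrees of freedom
#'
#' Degrees of freedom of the mean-and-covariance structure:
#' `p(p+3)/2` sample moments (p observed variables; means always counted)
#' minus the number of distinct free parameter labels. A negative value is
#' returned with a warning and an `"over-parameterized"` flag attribute rather
#' than silently.
#'
#' @param model a [path_model()].
#' @return Integer degrees of freedom (possibly flagged).
#' @export
model_df <- function(model) {
  validate_path_model(model)
  p <- length(model$observed)
  df <- as.integer(p * (p + 3) / 2 - length(free_labels(model)))
  if (df < 0) {
    warning("model has negative degrees of freedom (over-parameterized)")
    attr(df, "flag") <- "over-parameterized"
  }
  df
}

# Compile a model into index vectors for fast matrix filling. Positions are
# linear indices into the k x k matrices; symmetric entries are duplicated.
compile_path_model <- function(model) {
  validate_path_model(model)
  nodes <- model_nodes(model)
  k <- length(nodes)
  idx <- stats::setNames(seq_len(k), nodes)
  labs <- free_labels(model)
  par_of <- stats::setNames(seq_along(labs), labs)

  lin <- function(i, j) (j - 1L) * k + i # column-major

  p <- model$paths
  a_i <- idx[p$to]; a_j <- idx[p$from]
  a_free <- !is.na(p$label)
  cv <- model$covs
  s_i <- idx[cv$node1]; s_j <- idx[cv$node2]
  s_free <- !is.na(cv$label)
  # duplicate off-diagonal entries for symmetry
  off <- s_i != s_j
  s_pos <- c(lin(s_i, s_j), lin(s_j[off], s_i[off]))
  s_val <- c(cv$value, cv$value[off])
  s_par <- c(ifelse(s_free, par_of[cv$label], NA_integer_),
             ifelse(s_free[off], par_of[cv$label[off]], NA_integer_))
  s_isfree <- !is.na(s_par)

  mn <- model$means
  m_pos <- idx[mn$node]
  m_free <- !is.na(mn$label)

  s_all_i <- c(s_i, s_j[off])
  s_all_j <- c(s_j, s_i[off])
  list(
    nodes = nodes, k = k, obs = unname(idx[model$observed]),
    labels = labs,
    A_fix_pos = lin(a_i, a_j)[!a_free], A_fix_val = p$value[!a_free],
    A_free_pos = lin(a_i, a_j)[a_free], A_free_par = unname(par_of[p$label[a_free]]),
    A_free_i = unname(a_i[a_free]), A_free_j = unname(a_j[a_free]),
    S_fix_pos = s_pos[!s_isfree], S_fix_val = s_val[!s_isfree],
    S_free_pos = s_pos[s_isfree], S_free_par = s_par[s_isfree],
    S_free_i = unname(s_all_i[s_isfree]), S_free_j = unname(s_all_j[s_isfree]),
    M_fix_pos = m_pos[!m_free], M_fix_val = mn$value[!m_free],
    M_free_pos = m_pos[m_free], M_free_par = unname(par_of[mn$label[m_free]])
  )
}

# Fill A, S, M from an unnamed parameter vector in label order.
ram_matrices <- function(cm, theta) {
  k <- cm$k
  A <- matrix(0, k, k)
  if (length(cm$A_fix_pos)) A[cm$A_fix_pos] <- cm$A_fix_val
  if (length(cm$A_free_pos)) A[cm$A_free_pos] <- theta[cm$A_free_par]
  S <- matrix(0, k, k)
  if (length(cm$S_fix_pos)) S[cm$S_fix_pos] <- cm$S_fix_val
  if (length(cm$S_free_pos)) S[cm$S_free_pos] <- theta[cm$S_free_par]
  M <- numeric(k)
  if (length(cm$M_fix_pos)) M[cm$M_fix_pos] <- cm$M_fix_val
  if (length(cm$M_free_pos)) M[cm$M_free_pos] <- theta[cm$M_free_par]
  list(A = A, S = S, M = M)
}

check_values <- function(cm, values) {
  if (length(cm$labels) == 0) return(numeric())
  if (is.null(names(values)) || !all(cm$labels %in% names(values))) {
    missing <- setdiff(cm$labels, names(values) %||% character())
    stop("missing value(s) for free parameter label(s): ",
         paste(missing, collapse = ", "))
  }
  unname(unlist(values)[cm$labels])
}

#' Implied means and covariance of a path model
#'
#' Computes the model-implied moment pair by the total-effects identity of the
#' RAM formulation: with `T = (I - A)^-1`, the covariance over all nodes is
#' `T S T'` and the mean vector is `T M`; the observed block is returned in
#' the model's `observed` order.
#'
#' @param model a [path_model()].
#' @param values named vector (or list) assigning a value to every free label.
#' @return A list of class `moment_pair` with elements `mu` (named mean
#'   vector), `sigma` (covariance matrix over observed nodes), and the
#'   full-node versions `mu_full`, `sigma_full` (used for standardization).
#' @export
implied_moments <- function(model, values = numeric()) {
  cm <- compile_path_model(model)
  theta <- check_values(cm, values)
  mats <- ram_matrices(cm, theta)
  total <- solve(diag(cm$k) - mats$A)
  sigma_full <- total %*% mats$S %*% t(total)
  mu_full <- drop(total %*% mats$M)
  oi <- cm$obs
  structure(
    list(
      mu = stats::setNames(mu_full[oi], model$observed),
      sigma = structure(sigma_full[oi, oi, drop = FALSE],
                        dimnames = list(model$observed, model$observed)),
      mu_full = stats::setNames(mu_full, cm$nodes),
      sigma_full = structure(sigma_full, dimnames = list(cm$nodes, cm$nodes))
    ),
    class = "moment_pair"
  )
}

#' Saturated model over a set of observed variables
#'
#' All variances, covariances and means free, no directed paths: zero degrees
#' of freedom and perfect fit by construction.
#'
#' @param vars character vector of observed variable names.
#' @return A [path_model()].
#' @export
saturated_model <- function(vars) {
  m <- path_model(observed = vars)
  for (i in seq_along(vars)) {
    for (j in i:length(vars)) {
      m <- add_cov(m, vars[i], vars[j],
                   label = paste0("s_", vars[i], "_", vars[j]))
    }
    m <- add_mean(m, vars[i], label = paste0("m_", vars[i]))
  }
  m
}

#' Serialize / deserialize a path model as JSON
#'
#' @param model a [path_model()].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return `model_to_json()` returns the JSON string invisibly when writing to
#'   a file; `model_from_json()` returns a [path_model()].
#' @export
model_to_json <- function(model, path = NULL) {
  payload <- list(
    observed = model$observed, latent = model$latent,
    paths = model$paths, covs = model$covs, means = model$means
  )
  js <- jsonlite::toJSON(payload, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname model_to_json
#' @param json a JSON string or path to a JSON file.
#' @export
model_from_json <- function(json) {
  src <- if (file.exists(json)) json else json
  payload <- jsonlite::fromJSON(src, simplifyDataFrame = TRUE)
  m <- path_model(observed = payload$observed,
                  latent = payload$latent %||% character())
  as_entries <- function(df) {
    if (is.null(df) || length(df) == 0) return(NULL)
    df$label[is.null(df$label)] <- NA
    df
  }
  p <- as_entries(payload$paths)
  if (!is.null(p)) {
    for (r in seq_len(nrow(p))) {
      m <- add_path(m, p$from[r], p$to[r], p$value[r], p$label[r])
    }
  }
  cv <- as_entries(payload$covs)
  if (!is.null(cv)) {
    for (r in seq_len(nrow(cv))) {
      m <- add_cov(m, cv$node1[r], cv$node2[r], cv$value[r], cv$label[r])
    }
  }
  mn <- as_entries(payload$means)
  if (!is.null(mn)) {
    for (r in seq_len(nrow(mn))) {
      m <- add_mean(m, mn$node[r], mn$value[r], mn$label[r])
    }
  }
  m
}

#' @export
print.path_model <- function(x, ...) {
  nfree <- length(free_labels(x))
  cat(sprintf(
    "<path_model> %d observed + %d latent nodes; %d paths, %d (co)variances, %d means; %d free parameters\n",
    length(x$observed), length(x$latent),
    nrow(x$paths), nrow(x$covs), nrow(x$means), nfree
  ))
  invisible(x)
}
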