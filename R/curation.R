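# Manual model curation as an ordered, reversible edit list.

#' Construct a curation edit
#'
#' Supported actions:
#' * `add_reaction`: payload is a list with `id`, `name`, `stoichiometry`
#'   (named numeric), `lower_bound`, `upper_bound`, `is_exchange`, and
#'   optionally `metabolites` (data.frame rows to declare new metabolites).
#' * `remove_reaction`: payload is a list with `id`.
#' * `set_bounds`: payload has `id`, `lower_bound` and/or `upper_bound`.
#' * `set_formula`: payload has `metabolite_id` and `formula`.
#'
#' @param action one of `"add_reaction"`, `"remove_reaction"`, `"set_bounds"`,
#'   `"set_formula"`.
#' @param payload action-specific content (see details).
#' @param provenance_note free-text provenance (literature source etc.).
#' @return a `curation_edit` object.
#' @export
curation_edit <- function(action = c("add_reaction", "remove_reaction",
                                     "set_bounds", "set_formula"),
                          payload, provenance_note = "") {
  action <- match.arg(action)
  structure(list(action = action, payload = payload,
                 provenance_note = provenance_note),
            class = "curation_edit")
}

#' Apply curation edits to a network
#'
#' Edits are applied in order and atomically: if any edit fails, an error
#' naming the 1-based index of the failing edit is raised and the input
#' network is left untouched. The applied edits, together with the
#' information needed to revert them, are retained in the returned network's
#' `"curation_log"` attribute.
#'
#' @param net a `metabolic_network`.
#' @param edits list of `curation_edit` objects (or a single edit).
#' @return the edited, re-validated network.
#' @seealso [invert_edits()] for reversal, [read_curation_yaml()] for the
#'   on-disk format.
#' @export
apply_curation <- function(net, edits) {
  if (inherits(edits, "curation_edit")) edits <- list(edits)
  out <- net
  log <- attr(net, "curation_log") %||% list()
  for (i in seq_along(edits)) {
    step <- tryCatch(
      apply_one_edit(out, edits[[i]]),
      error = function(e) stop("curation edit ", i, " (",
                               edits[[i]]$action, ") failed: ",
                               conditionMessage(e), call. = FALSE)
    )
    out <- step$net
    log <- c(log, list(list(edit = edits[[i]], inverse = step$inverse)))
  }
  out <- validate_network(out)
  attr(out, "curation_log") <- log
  out
}

apply_one_edit <- function(net, edit) {
  stopifnot(inherits(edit, "curation_edit"))
  p <- edit$payload
  switch(edit$action,
    add_reaction = {
      if (p$id %in% net$reactions$id) stop("reaction already exists: ", p$id)
      if (!is.null(p$metabolites)) {
        new_m <- as.data.frame(p$metabolites, stringsAsFactors = FALSE)
        new_m <- new_m[!new_m$id %in% net$metabolites$id, , drop = FALSE]
        net$metabolites <- rbind(net$metabolites,
                                 new_m[, names(net$metabolites)])
      }
      net$reactions <- rbind(net$reactions, data.frame(
        id = p$id, name = p$name %||% p$id,
        lower_bound = as.numeric(p$lower_bound),
        upper_bound = as.numeric(p$upper_bound),
        is_exchange = isTRUE(p$is_exchange),
        stringsAsFactors = FALSE))
      net$stoichiometry[[p$id]] <- unlist(p$stoichiometry)
      inv <- curation_edit("remove_reaction", list(id = p$id),
                           "auto-inverse")
      list(net = net, inverse = inv)
    },
    remove_reaction = {
      i <- match(p$id, net$reactions$id)
      if (is.na(i)) stop("unknown reaction: ", p$id)
      if (p$id == net$biomass_reaction_id) {
        stop("cannot remove the biomass reaction")
      }
      old <- net$reactions[i, ]
      old_s <- net$stoichiometry[[p$id]]
      net$reactions <- net$reactions[-i, , drop = FALSE]
      rownames(net$reactions) <- NULL
      net$stoichiometry[[p$id]] <- NULL
      inv <- curation_edit("add_reaction", list(
        id = old$id, name = old$name, stoichiometry = old_s,
        lower_bound = old$lower_bound, upper_bound = old$upper_bound,
        is_exchange = old$is_exchange), "auto-inverse")
      list(net = net, inverse = inv)
    },
    set_bounds = {
      i <- match(p$id, net$reactions$id)
      if (is.na(i)) stop("unknown reaction: ", p$id)
      inv <- curation_edit("set_bounds", list(
        id = p$id,
        lower_bound = net$reactions$lower_bound[i],
        upper_bound = net$reactions$upper_bound[i]), "auto-inverse")
      if (!is.null(p$lower_bound)) {
        net$reactions$lower_bound[i] <- as.numeric(p$lower_bound)
      }
      if (!is.null(p$upper_bound)) {
        net$reactions$upper_bound[i] <- as.numeric(p$upper_bound)
      }
      list(net = net, inverse = inv)
    },
    set_formula = {
      i <- match(p$metabolite_id, net$metabolites$id)
      if (is.na(i)) stop("unknown metabolite: ", p$metabolite_id)
      inv <- curation_edit("set_formula", list(
        metabolite_id = p$metabolite_id,
        formula = net$metabolites$formula[i]), "auto-inverse")
      net$metabolites$formula[i] <- p$formula
      list(net = net, inverse = inv)
    }
  )
}

#' Inverse of an applied edit sequence
#'
#' Returns the edits that undo those recorded in a network's curation log
#' (most recent first), so that
#' `apply_curation(apply_curation(net, e), invert_edits(...))` restores the
#' original network content.
#'
#' @param net a network previously returned by [apply_curation()].
#' @return list of `curation_edit` objects.
#' @export
invert_edits <- function(net) {
  log <- attr(net, "curation_log")
  if (is.null(log)) return(list())
  lapply(rev(log), function(entry) entry$inverse)
}

#' Read curation edits from a YAML file
#'
#' The file holds one YAML document per edit, each with keys `action`,
#' `payload` and optional `provenance_note`; edits are applied in file order.
#'
#' @param path YAML file path.
#' @return list of `curation_edit` objects.
#' @export
read_curation_yaml <- function(path) {
  txt <- readLines(path, warn = FALSE)
  doc_id <- cumsum(grepl("^---\\s*$", txt))
  docs <- split(txt, doc_id)
  docs <- Filter(function(d) any(nzchar(trimws(sub("^---\\s*$", "", d)))),
                 docs)
  lapply(docs, function(d) {
    d <- yaml::yaml.load(paste(sub("^---\\s*$", "", d), collapse = "\n"))
    curation_edit(d$action, d$payload, d$provenance_note %||% "")
  })
}
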