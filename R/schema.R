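#' Fact schema: fact types, anchor slots, and modifier slots
#'
#' A fact schema declares the fact types an extractor recognises. Each fact
#' type owns exactly one named anchor slot (the contiguous entity span that
#' defines the fact: the finding, the recommendation, the diagnosis, ...) and
#' a set of named modifier slots (negation, uncertainty, location, size,
#' change over time, ...), each designed to answer one clinical question
#' about the anchor. The schema is a registry, not a hard-coded enumeration:
#' new fact types or slots require only a config edit, and the neural models
#' size their output layers from the registry.
#'
#' @param fact_types list of fact type definitions, each a list with elements
#'   `name`, `anchor`, and `modifiers` (a list of slot definitions; each
#'   either a slot name or a list with `name`, optional `question`, optional
#'   `required`).
#' @param version schema version string, stored in annotation file headers.
#' @return An object of class `rf_schema`.
#' @examples
#' sch <- rf_schema(list(list(name = "finding_observed", anchor = "finding",
#'                            modifiers = list("negation", "location"))))
#' fact_type_names(sch)
#' @export
rf_schema <- function(fact_types, version = "1.0") {
  stopifnot(is.list(fact_types), length(fact_types) >= 1L)
  fts <- lapply(fact_types, normalize_fact_type)
  nms <- vapply(fts, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("schema validation: duplicate fact type name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  anchors <- vapply(fts, `[[`, character(1), "anchor")
  if (anyDuplicated(anchors)) {
    stop("schema validation: anchor slot names must be unique across fact types: ",
         paste(unique(anchors[duplicated(anchors)]), collapse = ", "),
         call. = FALSE)
  }
  names(fts) <- nms
  structure(list(version = as.character(version), fact_types = fts),
            class = "rf_schema")
}

normalize_fact_type <- function(ft) {
  if (is.null(ft$name) || !nzchar(ft$name)) {
    stop("schema validation: fact type with empty name", call. = FALSE)
  }
  if (is.null(ft$anchor) || !nzchar(ft$anchor)) {
    stop("schema validation: fact type '", ft$name, "' needs exactly one anchor slot name",
         call. = FALSE)
  }
  mods <- lapply(ft$modifiers %||% list(), function(m) {
    if (is.character(m) && length(m) == 1L) m <- list(name = m)
    if (is.null(m$name) || !nzchar(m$name)) {
      stop("schema validation: fact type '", ft$name, "' has a modifier slot with empty name",
           call. = FALSE)
    }
    list(name = as.character(m$name),
         question = as.character(m$question %||% ""),
         required = isTRUE(m$required))
  })
  mnames <- vapply(mods, `[[`, character(1), "name")
  if (anyDuplicated(mnames)) {
    stop("schema validation: fact type '", ft$name, "' repeats modifier slot name(s): ",
         paste(unique(mnames[duplicated(mnames)]), collapse = ", "), call. = FALSE)
  }
  names(mods) <- mnames
  list(name = as.character(ft$name), anchor = as.character(ft$anchor),
       modifiers = mods)
}

#' @export
print.rf_schema <- function(x, ...) {
  cat("<rf_schema> version", x$version, "-", length(x$fact_types), "fact types\n")
  for (ft in x$fact_types) {
    cat(sprintf("  %-26s anchor=%-16s modifiers: %s\n", ft$name, ft$anchor,
                paste(names(ft$modifiers), collapse = ", ")))
  }
  invisible(x)
}

#' @rdname rf_schema
#' @param schema an `rf_schema` object.
#' @export
fact_type_names <- function(schema) names(schema$fact_types)

#' @rdname rf_schema
#' @export
anchor_names <- function(schema) {
  vapply(schema$fact_types, `[[`, character(1), "anchor")
}

#' @rdname rf_schema
#' @param fact_type name of a fact type in `schema`.
#' @export
modifier_slot_names <- function(schema, fact_type) {
  ft <- schema$fact_types[[fact_type]]
  if (is.null(ft)) stop("unknown fact type: ", fact_type, call. = FALSE)
  names(ft$modifiers)
}

# fact type owning a given anchor slot name, or NA
fact_type_for_anchor <- function(schema, anchor) {
  a <- anchor_names(schema)
  hit <- names(a)[a == anchor]
  if (length(hit)) hit[[1]] else NA_character_
}

#' Load and save schema configuration files
#'
#' The schema config dialect is YAML with two top-level keys: `version` and
#' `fact_types`. Each fact type entry has `name`, `anchor`, and an optional
#' `modifiers` list whose entries are either bare slot names or maps with
#' `name` / `question` / `required`. Unknown keys are rejected so typos in
#' hand-edited configs surface as errors rather than silently vanishing. The
#' default schema shipped with the package is at
#' `system.file("extdata", "default_schema.yaml", package = "radfacts")`.
#'
#' @param path path to a YAML schema config.
#' @return `load_schema()` returns an `rf_schema`; `save_schema()` writes
#'   `schema` to `path` and returns `path` invisibly. Saving then loading
#'   reproduces the registry exactly.
#' @examples
#' sch <- load_schema(default_schema_path())
#' @export
load_schema <- function(path) {
  if (!file.exists(path)) stop("schema config not found: ", path, call. = FALSE)
  doc <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("schema configuration error in '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  allowed_top <- c("version", "fact_types")
  extra <- setdiff(names(doc), allowed_top)
  if (length(extra)) {
    stop("schema configuration error: unknown top-level key(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (is.null(doc$fact_types) || !length(doc$fact_types)) {
    stop("schema configuration error: 'fact_types' missing or empty", call. = FALSE)
  }
  for (i in seq_along(doc$fact_types)) {
    extra <- setdiff(names(doc$fact_types[[i]]), c("name", "anchor", "modifiers"))
    if (length(extra)) {
      stop("schema configuration error: fact type entry ", i,
           " has unknown key(s): ", paste(extra, collapse = ", "), call. = FALSE)
    }
    mods <- doc$fact_types[[i]]$modifiers
    if (!is.null(mods)) for (m in mods) {
      if (is.list(m)) {
        extra <- setdiff(names(m), c("name", "question", "required"))
        if (length(extra)) {
          stop("schema configuration error: modifier entry in fact type '",
               doc$fact_types[[i]]$name, "' has unknown key(s): ",
               paste(extra, collapse = ", "), call. = FALSE)
        }
      }
    }
  }
  rf_schema(doc$fact_types, version = doc$version %||% "1.0")
}

#' @rdname load_schema
#' @param schema an `rf_schema` to serialise.
#' @export
save_schema <- function(schema, path) {
  stopifnot(inherits(schema, "rf_schema"))
  doc <- list(
    version = schema$version,
    fact_types = lapply(unname(schema$fact_types), function(ft) {
      list(name = ft$name, anchor = ft$anchor,
           modifiers = lapply(unname(ft$modifiers), function(m) {
             list(name = m$name, question = m$question, required = m$required)
           }))
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname load_schema
#' @export
default_schema_path <- function() {
  system.file("extdata", "default_schema.yaml", package = "radfacts",
              mustWork = TRUE)
}

#' @rdname load_schema
#' @export
default_schema <- function() load_schema(default_schema_path())

#' Validate a fact annotation against a schema
#'
#' Checks that the fact's type is registered, that the anchor is a single
#' contiguous token interval lying within the fact span, and that every
#' modifier slot is declared for the fact type with all its intervals inside
#' the fact span. Violations are returned as a character vector rather than
#' raised, so corpus-wide validation can aggregate them; an empty vector
#' means the fact is valid. Overlap among modifier spans, or between a
#' modifier and the anchor, is permitted.
#'
#' @param fact an [rf_fact()] annotation.
#' @param schema an `rf_schema`.
#' @param n_tokens optional token count of the host report; when given, span
#'   bounds are checked against it.
#' @return character vector of violation messages (empty if valid).
#' @export
validate_fact <- function(fact, schema, n_tokens = NULL) {
  stopifnot(inherits(schema, "rf_schema"))
  v <- character(0)
  ft <- schema$fact_types[[fact$fact_type]]
  if (is.null(ft)) {
    return(paste0("unknown fact type '", fact$fact_type, "'"))
  }
  if (!is_interval(fact$fact_span)) {
    return("fact span is not a valid token interval")
  }
  anchor_ivs <- as_interval_list(fact$anchor_span)
  bad_anchor <- !all(vapply(anchor_ivs, is_interval, logical(1)))
  if (bad_anchor) {
    v <- c(v, "anchor span is not a valid token interval")
  } else if (length(anchor_ivs) != 1L) {
    v <- c(v, "anchor not contiguous (anchor must be a single token interval)")
  } else {
    if (!interval_within(anchor_ivs[[1]], fact$fact_span)) {
      v <- c(v, "anchor span outside fact span")
    }
  }
  declared <- names(ft$modifiers)
  for (mod in fact$modifiers) {
    if (!mod$slot %in% declared) {
      v <- c(v, paste0("unknown slot '", mod$slot, "' for fact type '",
                       fact$fact_type, "'"))
      next
    }
    ivs <- mod$spans
    if (!length(ivs) || !all(vapply(ivs, is_interval, logical(1)))) {
      v <- c(v, paste0("slot '", mod$slot, "': invalid token interval"))
      next
    }
    if (!intervals_sorted_disjoint(ivs)) {
      v <- c(v, paste0("slot '", mod$slot, "': intervals not sorted/disjoint"))
    }
    if (!all(vapply(ivs, interval_within, logical(1), outer = fact$fact_span))) {
      v <- c(v, paste0("slot '", mod$slot, "': interval outside fact span"))
    }
  }
  if (!is.null(n_tokens) && is_interval(fact$fact_span) &&
      fact$fact_span[2] > n_tokens) {
    v <- c(v, "fact span beyond end of report")
  }
  v
}
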