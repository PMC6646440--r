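#' Synthetic gold-annotated radiology report generator
#'
#' Generates radiology-style report text together with exact gold fact
#' annotations, emulating the statistical structure the extractor assumes:
#' multi-fact prose sentences in telegraphic reporting style, optional
#' anatomic section headers, heavily skewed fact-type frequencies (findings
#' dominate; lab-result facts are rare), conjunction sentences that pack
#' several same-type facts into one shared text span, negation /
#' uncertainty / conditional modifiers, and typographic noise. Gold token
#' spans are computed from template slot positions; typos are injected only
#' inside word interiors so tokenization and gold indices stay valid.
#'
#' @param seed integer master seed.
#' @param n_reports number of reports for [generate_corpus()].
#' @param facts_per_report_mean,facts_per_report_dispersion negative-binomial
#'   parameters (mean and size) for the per-report fact count, truncated at 1.
#' @param fact_type_weights named nonnegative relative frequencies per fact
#'   type.
#' @param fact_type_caps named list capping the total number of facts of a
#'   type across a generated corpus (reproduces the rare-class regime: the
#'   default caps lab-result facts at 9 regardless of corpus size).
#' @param modifier_attach_probs named list `type -> slot -> probability`
#'   overriding the default attachment probability for optional modifier
#'   slots; `default_attach` is used for unlisted slots.
#' @param default_attach default attachment probability for optional slots.
#' @param conjunction_prob probability that a sentence packs 2-4 same-type
#'   facts (supported for finding and anatomic-region facts).
#' @param negation_rate,uncertainty_rate,conditional_rate attachment
#'   probabilities for the negation / uncertainty / conditionality slots
#'   wherever a template offers them.
#' @param typo_rate per-token probability of a single interior character
#'   substitution or transposition.
#' @param section_header_prob probability that a report uses anatomic
#'   section headers.
#' @return `generator_config()` returns a validated config list of class
#'   `rf_generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_reports = 120L,
                             facts_per_report_mean = 44.1,
                             facts_per_report_dispersion = 25,
                             fact_type_weights = NULL,
                             fact_type_caps = list(lab_result = 9L),
                             modifier_attach_probs = list(),
                             default_attach = 0.88,
                             conjunction_prob = 0.18,
                             negation_rate = 0.25,
                             uncertainty_rate = 0.18,
                             conditional_rate = 0.35,
                             typo_rate = 0.02,
                             section_header_prob = 0.6) {
  if (is.null(fact_type_weights)) {
    # skew mirrors the corpus regime the extractor is built for: roughly
    # half of all facts are imaging findings, lab results are vanishingly
    # rare, procedures/diagnoses each stay in the low hundreds per ~5000.
    fact_type_weights <- c(finding_observed = 0.47,
                           anatomic_region_property = 0.16,
                           followup_recommendation = 0.08,
                           clinical_history = 0.07,
                           prior_study = 0.05,
                           comparison_study = 0.05,
                           had_procedure = 0.035,
                           carries_diagnosis = 0.035,
                           imaging_limitation = 0.03,
                           lab_result = 0.008)
  }
  probs <- c(conjunction_prob, negation_rate, uncertainty_rate,
             conditional_rate, typo_rate, section_header_prob, default_attach)
  stopifnot(all(probs >= 0 & probs <= 1),
            all(fact_type_weights >= 0), sum(fact_type_weights) > 0,
            facts_per_report_mean > 0, facts_per_report_dispersion > 0,
            n_reports >= 1)
  structure(list(seed = as.integer(seed), n_reports = as.integer(n_reports),
                 facts_per_report_mean = facts_per_report_mean,
                 facts_per_report_dispersion = facts_per_report_dispersion,
                 fact_type_weights = fact_type_weights / sum(fact_type_weights),
                 fact_type_caps = fact_type_caps,
                 modifier_attach_probs = modifier_attach_probs,
                 default_attach = default_attach,
                 conjunction_prob = conjunction_prob,
                 negation_rate = negation_rate,
                 uncertainty_rate = uncertainty_rate,
                 conditional_rate = conditional_rate,
                 typo_rate = typo_rate,
                 section_header_prob = section_header_prob),
            class = "rf_generator_config")
}

# --- template bank ----------------------------------------------------------
# A template is a list of parts. Part kinds:
#   txt   - literal tokens, always emitted, inside the fact span
#   anch  - the anchor slot; lex gives the lexicon key
#   mod   - an optional modifier slot; parts sharing `group` attach jointly
#           (a slot realised by two parts yields a discontiguous gold span)
#   punct - literal tokens outside the fact span (sentence-final period)
p_txt <- function(...) list(kind = "txt", toks = c(...))
# literal tokens emitted only when `group` attaches (connective commas)
p_gtxt <- function(group, ...) list(kind = "gtxt", group = group, toks = c(...))
p_anch <- function(lex) list(kind = "anch", lex = lex)
p_mod <- function(slot, lex, group = NULL) {
  list(kind = "mod", slot = slot, lex = lex, group = group %||% slot)
}
p_end <- function() list(kind = "punct", toks = ".")

#' @rdname generator_config
#' @details `default_template_bank()` returns the built-in sentence
#'   templates and filler lexicons (organs, lesion terms, sizes with units,
#'   change phrases, timing phrases, negation / uncertainty / conditional
#'   cues). Every template names exactly one anchor slot, and every slot a
#'   template offers is declared for its fact type in the default schema.
#' @export
default_template_bank <- function() {
  organs <- list("liver", "spleen", "pancreas", c("right", "kidney"),
                 c("left", "kidney"), c("pancreatic", "tail"),
                 c("left", "hepatic", "lobe"), "pelvis",
                 c("right", "lower", "quadrant"), c("gallbladder", "fossa"),
                 c("common", "bile", "duct"), "retroperitoneum")
  locs <- list()
  for (prep in c("in", "within")) {
    for (o in organs) locs <- c(locs, list(c(prep, "the", o)))
  }
  lex <- list(
    finding = list("lesion", "cyst", "mass", "nodule", "calcification",
                   "stone", "thrombus", "aneurysm", "hernia", "ascites",
                   "lymphadenopathy", "stranding", c("fluid", "collection"),
                   "diverticulosis", c("fatty", "infiltration"),
                   c("biliary", "ductal", "dilatation"), "effusion"),
    recommendation = list(c("ultrasound", "followup"), c("mri", "correlation"),
                          c("dedicated", "ct"), c("clinical", "correlation"),
                          c("repeat", "imaging"), c("interval", "followup")),
    diagnosis = list("cholelithiasis", "cirrhosis", "pancreatitis",
                     "appendicitis", "diverticulitis", "pyelonephritis",
                     c("metastatic", "disease"), "cholecystitis",
                     "nephrolithiasis", c("sidebranch", "ipmn")),
    procedure = list("cholecystectomy", "appendectomy", "hysterectomy",
                     "nephrectomy", c("liver", "biopsy"), "colectomy",
                     c("hernia", "repair")),
    lab_value = list("creatinine", "bilirubin", "lipase", "amylase",
                     c("white", "count")),
    prior_study_name = list(c("ct", "abdomen"), c("mri", "abdomen"),
                            c("ultrasound", "study"), c("pet", "ct")),
    comparison_name = list(c("prior", "ct"), c("prior", "mri"),
                           c("outside", "ultrasound"),
                           c("previous", "radiograph")),
    region = list(c("hepatic", "artery"), c("portal", "vein"),
                  c("hepatic", "veins"), "gallbladder", "spleen", "pancreas",
                  "appendix", c("adrenal", "glands"), "aorta",
                  c("urinary", "bladder"), "uterus", "prostate", "liver",
                  "kidneys", "bowel"),
    history_item = list(c("abdominal", "pain"), "fever", c("weight", "loss"),
                        "nausea", c("flank", "pain"), "jaundice",
                        c("renal", "colic"), "hematuria"),
    limitation = list(c("limited", "evaluation"), c("nondiagnostic", "study"),
                      c("suboptimal", "evaluation")),
    limit_cause = list(c("motion", "artifact"), c("body", "habitus"),
                       c("streak", "artifact"), c("bowel", "gas")),
    location = locs,
    size = list(c("3", "mm"), c("5", "mm"), c("7", "mm"), c("9", "mm"),
                c("1.2", "cm"), c("2.4", "cm"), c("3.1", "cm"),
                c("4", "x", "3", "cm")),
    description = list("hypodense", "hyperenhancing", "cystic", "solid",
                       "calcified", "ill-defined", "well-circumscribed",
                       "spiculated", "nonaggressive", "heterogeneous",
                       "hypoechoic", "septated"),
    property = list("unremarkable", "patent", c("within", "normal", "limits"),
                    c("normal", "in", "appearance"), "atrophic",
                    c("surgically", "absent"), "distended", "decompressed",
                    "visualized"),
    change = list(c("unchanged", "from", "prior", "exam"), "stable",
                  c("slightly", "increased", "in", "size"),
                  c("decreased", "in", "size"),
                  c("new", "from", "prior", "study"), c("grossly", "stable")),
    timing = list(c("in", "3", "months"), c("in", "6", "months"),
                  c("within", "1", "year"), c("in", "12", "months")),
    temporal = list(c("in", "2015"), c("in", "2017"),
                    c("several", "years", "ago"),
                    c("since", "the", "prior", "exam"), "remote"),
    uncertainty_cue = list(c("possibly", "representing"),
                           c("may", "represent"), "likely",
                           c("suspicious", "for"), "probably"),
    conditional_cue = list(c("if", "clinically", "indicated"),
                           c("if", "symptoms", "persist"),
                           c("if", "there", "is", "concern", "for",
                             "malignancy")),
    reasoning = list(c("compatible", "with", "benign", "etiology"),
                     c("given", "the", "enhancement", "pattern"),
                     c("consistent", "with", "prior", "imaging")),
    finding_verb = list("seen", "identified", "noted", "present",
                        "demonstrated"),
    labval = list("2.1", "1.4", "3.6", "11.2", "0.8")
  )
  templates <- list(
    finding_observed = list(
      list(p_mod("negation", "No"), p_mod("size", "$size"),
           p_mod("description", "$description"), p_anch("$finding"),
           p_anch_verb(), p_mod("location", "$location"),
           p_mod("change_over_time", "$change"), p_end()),
      list(p_mod("negation", "No"),
           p_mod("uncertainty", "$uncertainty_cue"),
           p_mod("size", "$size"), p_anch("$finding"),
           p_mod("location", "$location"),
           p_gtxt("diagnostic_reasoning", ","),
           p_mod("diagnostic_reasoning", "$reasoning"), p_end()),
      list(p_mod("negation", "No"), p_mod("description", "$description",
                                          group = "descpair"),
           p_gtxt("descpair", ","), p_mod("description", "$description",
                                          group = "descpair"),
           p_anch("$finding"), p_mod("location", "$location"),
           p_mod("temporal_qualifier", "$temporal"), p_end())
    ),
    followup_recommendation = list(
      list(p_txt("Recommend"), p_anch("$recommendation"),
           p_mod("desired_timing", "$timing"),
           p_mod("conditionality", "$conditional_cue"), p_end()),
      list(p_anch("$recommendation"), p_txt("is", "recommended"),
           p_mod("desired_timing", "$timing"),
           p_mod("location", "$location"), p_end()),
      list(p_mod("negation", "No"), p_anch("$recommendation"),
           p_txt("necessary"), p_end())
    ),
    carries_diagnosis = list(
      list(p_txt("Known"), p_mod("uncertainty", "$uncertainty_cue"),
           p_anch("$diagnosis"), p_mod("temporal_qualifier", "$temporal"),
           p_end()),
      list(p_txt("Patient", "carries", "a", "diagnosis", "of"),
           p_anch("$diagnosis"), p_end()),
      list(p_mod("person_qualifier", "Family"), p_txt("history", "of"),
           p_anch("$diagnosis"), p_end())
    ),
    had_procedure = list(
      list(p_txt("Status", "post"), p_anch("$procedure"),
           p_mod("temporal_qualifier", "$temporal"), p_end()),
      list(p_txt("The", "patient", "has", "undergone"), p_anch("$procedure"),
           p_mod("location", "$location"), p_end()),
      list(p_txt("Patient"), p_mod("negation", "without"), p_txt("prior"),
           p_anch("$procedure"), p_end())
    ),
    lab_result = list(
      list(p_anch("$lab_value"), p_txt("is", "elevated", "at"),
           p_mod("description", "$labval"),
           p_mod("temporal_qualifier", "$temporal"), p_end()),
      list(p_anch("$lab_value"), p_txt("of"), p_mod("description", "$labval"),
           p_txt("noted"), p_end())
    ),
    prior_study = list(
      list(p_txt("Prior"), p_anch("$prior_study_name"), p_txt("performed"),
           p_mod("temporal_qualifier", "$temporal"), p_end()),
      list(p_mod("description", "contrast-enhanced"),
           p_anch("$prior_study_name"), p_txt("available", "for", "review"),
           p_end())
    ),
    comparison_study = list(
      list(p_txt("Comparison", "is", "made", "to"),
           p_anch("$comparison_name"),
           p_mod("temporal_qualifier", "$temporal"), p_end()),
      list(p_txt("Compared", "with"), p_anch("$comparison_name"),
           p_mod("description", c("of", "the", "abdomen")), p_end())
    ),
    anatomic_region_property = list(
      list(p_txt("The"), p_anch("$region"), p_txt("is"),
           p_mod("negation", "not"), p_mod("description", "$property"),
           p_mod("change_over_time", "$change"), p_end())
    ),
    clinical_history = list(
      list(p_txt("Clinical", "history", "of"), p_anch("$history_item"),
           p_mod("temporal_qualifier", "$temporal"), p_end()),
      list(p_txt("Patient", "presents", "with"), p_anch("$history_item"),
           p_end()),
      list(p_txt("Patient"), p_mod("negation", "denies"),
           p_anch("$history_item"), p_end()),
      list(p_mod("person_qualifier", "Family"), p_txt("history", "of"),
           p_anch("$history_item"), p_end())
    ),
    imaging_limitation = list(
      list(p_anch("$limitation"), p_txt("due", "to"),
           p_mod("description", "$limit_cause"),
           p_mod("location", "$location"), p_end())
    )
  )
  headers <- list(c("LIVER", ":"), c("SPLEEN", ":"), c("PANCREAS", ":"),
                  c("KIDNEYS", ":"), c("PELVIS", ":"), c("BOWEL", ":"),
                  c("VASCULATURE", ":"), c("IMPRESSION", ":"))
  list(lex = lex, templates = templates, headers = headers)
}

# anchor-adjacent verb; emitted as plain text
p_anch_verb <- function() list(kind = "txt", toks = NULL, lex = "$finding_verb")

sample_lex <- function(bank, ref) {
  if (is.character(ref) && length(ref) >= 1 && startsWith(ref[1], "$")) {
    key <- substring(ref[1], 2)
    entries <- bank$lex[[key]]
    if (is.null(entries)) stop("template bank: unknown lexicon key '", key, "'")
    e <- entries[[sample.int(length(entries), 1L)]]
    return(as.character(e))
  }
  as.character(ref)
}

attach_prob <- function(config, type, slot) {
  override <- config$modifier_attach_probs[[type]][[slot]]
  if (!is.null(override)) return(override)
  switch(slot,
         negation = config$negation_rate,
         uncertainty = config$uncertainty_rate,
         conditionality = config$conditional_rate,
         config$default_attach)
}

# Realize one single-fact sentence. Returns tokens plus spans relative to
# the sentence start.
realize_sentence <- function(type, bank, config) {
  tpls <- bank$templates[[type]]
  if (is.null(tpls)) {
    stop("generator configuration error: fact type '", type,
         "' has nonzero weight but no templates", call. = FALSE)
  }
  tpl <- tpls[[sample.int(length(tpls), 1L)]]
  groups <- unique(vapply(Filter(function(p) p$kind == "mod", tpl),
                          `[[`, character(1), "group"))
  slot_of_group <- list()
  for (p in tpl) if (p$kind == "mod") slot_of_group[[p$group]] <- p$slot
  attach <- vapply(groups, function(g) {
    stats::runif(1) < attach_prob(config, type, slot_of_group[[g]])
  }, logical(1))
  names(attach) <- groups
  toks <- character(0)
  anchor_iv <- NULL
  mods <- list()  # slot -> list of intervals
  fact_lo <- Inf; fact_hi <- -Inf
  for (p in tpl) {
    if (p$kind %in% c("mod", "gtxt") && !attach[[p$group]]) next
    part_toks <- if (p$kind %in% c("txt", "gtxt", "punct") && !is.null(p$toks)) {
      p$toks
    } else {
      sample_lex(bank, p$lex)
    }
    s <- length(toks)
    toks <- c(toks, part_toks)
    e <- length(toks)
    if (p$kind == "punct") next
    fact_lo <- min(fact_lo, s); fact_hi <- max(fact_hi, e)
    if (p$kind == "anch") anchor_iv <- c(s, e)
    if (p$kind == "mod") {
      mods[[p$slot]] <- c(mods[[p$slot]] %||% list(), list(c(s, e)))
    }
  }
  # drop dangling plain-text commas at the labeled-span edge (e.g. the
  # reasoning template when the reasoning slot is unattached)
  list(tokens = toks,
       facts = list(list(type = type, fact = c(fact_lo, fact_hi),
                         anchor = anchor_iv, mods = mods)))
}

# Conjunction sentence: 2-4 same-type facts sharing one clause.
realize_conjunction <- function(type, k, bank, config) {
  if (type == "anatomic_region_property") {
    anchors <- bank$lex$region[sample.int(length(bank$lex$region), k)]
    prop <- sample_lex(bank, "$property")
    toks <- "The"
    anchor_ivs <- list()
    for (i in seq_len(k)) {
      if (i > 1) toks <- c(toks, if (i == k) c(",", "and") else ",")
      s <- length(toks); toks <- c(toks, as.character(anchors[[i]]))
      anchor_ivs[[i]] <- c(s, length(toks))
    }
    toks <- c(toks, "are")
    negated <- stats::runif(1) < config$negation_rate
    neg_iv <- NULL
    if (negated) { s <- length(toks); toks <- c(toks, "not"); neg_iv <- c(s, s + 1) }
    s <- length(toks); toks <- c(toks, prop); prop_iv <- c(s, length(toks))
    fact_iv <- c(0, length(toks))
    toks <- c(toks, ".")
    facts <- lapply(anchor_ivs, function(aiv) {
      mods <- list(description = list(prop_iv))
      if (negated) mods$negation <- list(neg_iv)
      list(type = type, fact = fact_iv, anchor = aiv, mods = mods)
    })
  } else {  # finding_observed
    anchors <- bank$lex$finding[sample.int(length(bank$lex$finding), k)]
    negated <- stats::runif(1) < config$negation_rate
    toks <- character(0)
    neg_iv <- NULL
    if (negated) { toks <- "No"; neg_iv <- c(0, 1) } else toks <- c("There", "are")
    anchor_ivs <- list()
    for (i in seq_len(k)) {
      if (i > 1) toks <- c(toks, if (i == k) c(",", "and") else ",")
      s <- length(toks); toks <- c(toks, as.character(anchors[[i]]))
      anchor_ivs[[i]] <- c(s, length(toks))
    }
    if (negated) toks <- c(toks, sample_lex(bank, "$finding_verb"))
    s <- length(toks); toks <- c(toks, sample_lex(bank, "$location"))
    loc_iv <- c(s, length(toks))
    fact_iv <- c(0, length(toks))
    toks <- c(toks, ".")
    facts <- lapply(anchor_ivs, function(aiv) {
      mods <- list(location = list(loc_iv))
      if (negated) mods$negation <- list(neg_iv)
      list(type = type, fact = fact_iv, anchor = aiv, mods = mods)
    })
  }
  list(tokens = toks, facts = facts)
}

conjunction_types <- c("finding_observed", "anatomic_region_property")

inject_typos <- function(toks, typo_rate) {
  if (typo_rate <= 0) return(toks)
  for (i in seq_along(toks)) {
    w <- toks[i]
    if (nchar(w) >= 4 && grepl("^[a-z]+$", w) && stats::runif(1) < typo_rate) {
      pos <- sample.int(nchar(w) - 2L, 1L) + 1L  # interior position
      ch <- strsplit(w, "", fixed = TRUE)[[1]]
      if (stats::runif(1) < 0.5) {
        ch[pos] <- sample(letters, 1L)
      } else {
        tmp <- ch[pos]; ch[pos] <- ch[pos + 1L]; ch[pos + 1L] <- tmp
      }
      toks[i] <- paste(ch, collapse = "")
    }
  }
  toks
}

#' Generate one synthetic annotated report
#'
#' Deterministic given `(config$seed, report_index)`. Every emitted fact
#' passes [validate_fact()] against the default schema, and re-tokenizing
#' the generated text reproduces exactly the token stream the gold spans
#' index.
#'
#' @param config an [generator_config()] object.
#' @param report_index 1-based report number (part of the random stream
#'   derivation).
#' @param bank template bank, by default [default_template_bank()].
#' @param n_facts optional fixed fact count overriding the configured
#'   distribution.
#' @param type_budget optional named vector of remaining per-type fact
#'   budgets (used by [generate_corpus()] to enforce `fact_type_caps`);
#'   types at budget 0 are excluded from sampling.
#' @return an `rf_annotated` report.
#' @export
generate_report <- function(config, report_index,
                            bank = default_template_bank(),
                            n_facts = NULL, type_budget = NULL) {
  stopifnot(inherits(config, "rf_generator_config"))
  with_local_seed(derive_seed(config$seed, report_index), {
    weights <- config$fact_type_weights
    for (ty in names(weights)) {
      if (weights[[ty]] > 0 && is.null(bank$templates[[ty]])) {
        stop("generator configuration error: fact type '", ty,
             "' has nonzero weight but no templates", call. = FALSE)
      }
    }
    if (is.null(n_facts)) {
      n_facts <- max(1L, stats::rnbinom(
        1, size = config$facts_per_report_dispersion,
        mu = config$facts_per_report_mean))
    }
    budget <- type_budget
    pick_type <- function() {
      w <- weights
      if (!is.null(budget)) {
        blocked <- names(budget)[budget <= 0]
        w[names(w) %in% blocked] <- 0
        if (sum(w) == 0) w <- weights  # all capped: fall back
      }
      sample(names(w), 1L, prob = w)
    }
    # build sentences until n_facts facts emitted
    sentences <- list()
    emitted <- 0L
    while (emitted < n_facts) {
      ty <- pick_type()
      remaining <- n_facts - emitted
      if (ty %in% conjunction_types && remaining >= 2L &&
          stats::runif(1) < config$conjunction_prob) {
        k <- sample(2:min(4L, remaining), 1L)
        sent <- realize_conjunction(ty, k, bank, config)
      } else {
        sent <- realize_sentence(ty, bank, config)
      }
      sentences <- c(sentences, list(sent))
      emitted <- emitted + length(sent$facts)
      if (!is.null(budget) && ty %in% names(budget)) {
        budget[[ty]] <- budget[[ty]] - length(sent$facts)
      }
    }
    use_headers <- stats::runif(1) < config$section_header_prob
    toks <- character(0)
    facts <- list()
    i <- 1L
    header_i <- 1L
    n_sent <- length(sentences)
    while (i <= n_sent) {
      block <- sample(3:8, 1L)
      if (use_headers) {
        h <- bank$headers[[(header_i - 1L) %% length(bank$headers) + 1L]]
        header_i <- header_i + 1L
        toks <- c(toks, h)
      }
      for (j in i:min(n_sent, i + block - 1L)) {
        off <- length(toks)
        toks <- c(toks, sentences[[j]]$tokens)
        for (f in sentences[[j]]$facts) {
          mods <- lapply(f$mods, function(ivs) lapply(ivs, function(iv) iv + off))
          facts <- c(facts, list(
            rf_fact(f$type, f$fact + off, f$anchor + off, modifiers = mods)))
        }
      }
      i <- i + block
    }
    toks <- inject_typos(toks, config$typo_rate)
    text <- paste(toks, collapse = " ")
    report <- tokenize_report(
      text, report_id = sprintf("synth-%06d", report_index),
      metadata = list(modality = sample(c("CT", "MRI", "US"), 1L,
                                        prob = c(50, 48, 22))))
    stopifnot(nrow(report$tokens) == length(toks))
    annotated_report(report, facts)
  })
}

#' Generate a synthetic annotated corpus
#'
#' @inheritParams generate_report
#' @param n_facts_total optional exact total fact count for the corpus,
#'   apportioned over reports by largest remainder (useful for fixing
#'   corpus-level statistics exactly).
#' @return list of `rf_annotated` reports of length `config$n_reports`.
#' @export
generate_corpus <- function(config, bank = default_template_bank(),
                            n_facts_total = NULL) {
  n <- config$n_reports
  per_report <- NULL
  if (!is.null(n_facts_total)) {
    stopifnot(n_facts_total >= n)
    base <- rep(floor(n_facts_total / n), n)
    extra <- n_facts_total - sum(base)
    if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1
    per_report <- as.integer(base)
  }
  budget <- NULL
  if (length(config$fact_type_caps)) {
    budget <- unlist(config$fact_type_caps)
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ar <- generate_report(config, i, bank = bank,
                          n_facts = per_report[i], type_budget = budget)
    if (!is.null(budget)) {
      tys <- vapply(ar$facts, `[[`, character(1), "fact_type")
      for (ty in names(budget)) {
        budget[[ty]] <- budget[[ty]] - sum(tys == ty)
      }
    }
    out[[i]] <- ar
  }
  out
}
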