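# Independent oracles and fixture builders shared across the suite. Each
# oracle re-derives its answer from first principles (different algorithm
# and data layout than the implementation it checks).

`%||%` <- function(a, b) if (is.null(a)) b else a

make_inv <- function(owner = xr_user("alice"), sources = list(ontology_source("TOY"))) {
  create_investigation("Test investigation", sources, owner)
}

make_study <- function(owner = xr_user("alice")) {
  add_study(make_inv(owner), "Test study", owner)
}

make_registry_with <- function(...) {
  reg <- protocol_registry()
  protos <- lapply(list(...), function(nm) {
    register_protocol(reg, nm, paste("Body of", nm), "alice")
  })
  names(protos) <- unlist(list(...))
  list(registry = reg, protocols = protos)
}

# Deep copy of a study environment (nodes/arcs are plain lists, so copying
# the fields copies the graph).
clone_study <- function(st) {
  cp <- new.env(parent = emptyenv())
  for (f in ls(st)) assign(f, get(f, envir = st), envir = cp)
  class(cp) <- class(st)
  cp
}

## ---- brute-force graph invariant checker ------------------------------

# Re-checks every structural invariant independently: explicit pair table,
# parent counts from a raw edge matrix, recursive-DFS cycle detection and
# adjacency-list reachability.
bf_check <- function(st) {
  codes <- character(0)
  kind <- vapply(st$nodes, function(n) n$kind, character(1))
  edges <- if (length(st$arcs)) {
    do.call(rbind, lapply(st$arcs, function(a) {
      data.frame(p = a$parent_id, c = a$child_id, pa = !is.null(a$protocol_application),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(p = character(0), c = character(0), pa = logical(0))
  }

  root_ids <- names(kind)[kind == "root"]
  if (length(root_ids) != 1L || root_ids[1] %in% edges$c) codes <- c(codes, "UNIQUE_ROOT")

  ok_pairs <- c("root>biosource", "biosource>container", "container>container",
                "container>assay")
  for (i in seq_len(nrow(edges))) {
    pk <- kind[edges$p[i]]; ck <- kind[edges$c[i]]
    if (is.na(pk) || is.na(ck) || !paste0(pk, ">", ck) %in% ok_pairs) {
      codes <- c(codes, "ILLEGAL_CHILD")
    }
    if (!is.na(pk) && pk == "root" && edges$pa[i]) codes <- c(codes, "ROOT_ARC_PROTOCOL")
  }

  for (id in names(kind)) {
    if (sum(edges$c == id) > 1L && kind[[id]] %in% c("root", "biosource")) {
      codes <- c(codes, "MULTIPARENT_KIND")
    }
  }

  # recursive DFS with colouring for cycles
  colour <- stats::setNames(rep(0L, length(kind)), names(kind))
  cyclic <- FALSE
  visit <- function(v) {
    colour[[v]] <<- 1L
    for (w in edges$c[edges$p == v]) {
      if (colour[[w]] == 1L) cyclic <<- TRUE
      else if (colour[[w]] == 0L) visit(w)
    }
    colour[[v]] <<- 2L
  }
  for (v in names(kind)) if (colour[[v]] == 0L) visit(v)
  if (cyclic) codes <- c(codes, "CYCLE")

  if (length(root_ids) == 1L) {
    seen <- character(0)
    stack <- root_ids
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (v %in% seen) next
      seen <- c(seen, v)
      stack <- c(stack, edges$c[edges$p == v])
    }
    if (length(setdiff(names(kind), seen))) codes <- c(codes, "DISCONNECTED")
  }
  unique(codes)
}

## ---- single-edit corruptions ------------------------------------------

raw_add_arc <- function(st, parent, child, pa = NULL) {
  st$arc_counter <- st$arc_counter + 1L
  id <- paste0("x", st$arc_counter)
  st$arcs[[id]] <- list(id = id, parent_id = parent, child_id = child,
                        protocol_application = pa, attachments = list())
  st
}

node_ids_of_kind <- function(st, k) {
  names(Filter(function(n) n$kind == k, st$nodes))
}

# Each corruption returns a corrupted clone, or NULL when not applicable to
# this graph. All are single edits that break at least one invariant.
graph_corruptions <- list(
  second_root = function(st) {
    st <- clone_study(st)
    st$nodes[["zroot"]] <- list(id = "zroot", kind = "root", label = "extra root",
                                annotations = list(), attachments = list())
    st
  },
  kind_flip = function(st) {
    conts <- node_ids_of_kind(st, "container")
    if (!length(conts)) return(NULL)
    st <- clone_study(st)
    st$nodes[[conts[[1]]]]$kind <- "biosource"
    st$nodes[[conts[[1]]]]$miabs <- character(0)
    st
  },
  root_arc_protocol = function(st) {
    root_arcs <- Filter(function(a) a$parent_id == st$root_id, st$arcs)
    if (!length(root_arcs)) return(NULL)
    st <- clone_study(st)
    st$arcs[[root_arcs[[1]]$id]]$protocol_application <-
      list(protocol_id = "p1", protocol_name = "illegal", action = "",
           parameters = list())
    st
  },
  detach_node = function(st) {
    bios <- node_ids_of_kind(st, "biosource")
    if (!length(bios)) return(NULL)
    st <- clone_study(st)
    st$arcs <- Filter(function(a) a$child_id != bios[[1]], st$arcs)
    st
  },
  container_cycle = function(st) {
    bios <- node_ids_of_kind(st, "biosource")
    if (!length(bios)) return(NULL)
    st <- clone_study(st)
    for (id in c("zc1", "zc2")) {
      st$nodes[[id]] <- list(id = id, kind = "container", label = id,
                             annotations = list(), attachments = list())
    }
    st <- raw_add_arc(st, bios[[1]], "zc1")
    st <- raw_add_arc(st, "zc1", "zc2")
    raw_add_arc(st, "zc2", "zc1")
  },
  pooled_biosource = function(st) {
    bios <- node_ids_of_kind(st, "biosource")
    if (!length(bios)) return(NULL)
    st <- clone_study(st)
    raw_add_arc(st, st$root_id, bios[[1]])
  },
  backward_arc = function(st) {
    conts <- node_ids_of_kind(st, "container")
    if (!length(conts)) return(NULL)
    st <- clone_study(st)
    raw_add_arc(st, conts[[1]], st$root_id)
  }
)

## ---- random construction sequences ------------------------------------

# Builds a study through random public construction operations only
# (add_child / pool / bulk_add_children / duplicate_biosource), so the
# result must always validate clean.
random_ops_study <- function(seed, n_ops = 15L) {
  set.seed(seed)
  st <- make_study()
  prs <- make_registry_with("op protocol")
  add_child(st, st$root_id, "biosource", "b0")
  for (i in seq_len(n_ops)) {
    bios <- node_ids_of_kind(st, "biosource")
    conts <- node_ids_of_kind(st, "container")
    op <- sample(c("biosource", "container", "assay", "pool", "bulk",
                   "duplicate"), 1L)
    if (op == "biosource") {
      add_child(st, st$root_id, "biosource", paste0("b", i))
    } else if (op == "container") {
      parent <- sample(c(bios, conts), 1L)
      node <- add_child(st, parent, "container", paste0("c", i))
      arc <- st$arcs[[length(st$arcs)]]
      if (runif(1) < 0.5) {
        apply_protocol(st, arc$id, prs$protocols[[1]], action = "dev")
      }
    } else if (op == "assay" && length(conts)) {
      add_child(st, sample(conts, 1L), "assay", paste0("a", i),
                modality = sample(c("sequencing", "imaging"), 1L))
    } else if (op == "pool") {
      pool_from <- if (runif(1) < 0.5 && length(bios) >= 2L) bios else conts
      if (length(pool_from) >= 2L) {
        kmax <- min(3L, length(pool_from))
        k <- if (kmax == 2L) 2L else sample(2:kmax, 1L)
        pool(st, sample(pool_from, k), "container", paste0("pc", i))
      }
    } else if (op == "bulk" && length(bios)) {
      bulk_add_children(st, sample(bios, min(2L, length(bios))), "container",
                        paste0("bc", i, "_"))
    } else if (op == "duplicate" && length(bios)) {
      duplicate_biosource(st, sample(bios, 1L))
    }
  }
  st
}

## ---- brute-force term search oracle -----------------------------------

# Per-term loop over the raw stanza fields; recomputes case folding,
# token sets and ordering from scratch.
bf_search <- function(index, query, sources = NULL, limit = 20L) {
  q <- tolower(trimws(query))
  out <- data.frame(query = character(0), accession = character(0),
                    name = character(0), source = character(0),
                    match_type = character(0), score = numeric(0),
                    stringsAsFactors = FALSE)
  if (!nzchar(q)) return(out)
  qtok <- unique(strsplit(q, "[ \t]+")[[1]])
  scores <- c(exact_name = 1, exact_synonym = 0.9, token = 0.7, substring = 0.5)
  for (i in seq_len(index$term_count)) {
    if (!is.null(sources) && !index$source[[i]] %in% sources) next
    if (index$obsolete[[i]]) next
    nm <- tolower(index$name[[i]])
    syns <- tolower(vapply(index$synonyms[[i]], function(s) s$text, character(1)))
    texts <- c(nm, syns)
    toks <- unique(unlist(strsplit(texts, "[ \t]+")))
    mt <- if (q == nm) "exact_name"
      else if (q %in% syns) "exact_synonym"
      else if (all(qtok %in% toks)) "token"
      else if (any(vapply(texts, function(t) grepl(q, t, fixed = TRUE), logical(1)))) "substring"
      else NA_character_
    if (!is.na(mt)) {
      out <- rbind(out, data.frame(query = query, accession = index$accession[[i]],
                                   name = index$name[[i]], source = index$source[[i]],
                                   match_type = mt, score = unname(scores[[mt]]),
                                   stringsAsFactors = FALSE))
    }
  }
  out <- out[order(-out$score, out$accession), , drop = FALSE]
  out <- head(out, limit)
  rownames(out) <- NULL
  out
}

# Flat-table search oracle used for large corpora: a second independent
# route built from inverted token and synonym tables.
make_flat_oracle <- function(index) {
  n <- index$term_count
  name_lc <- tolower(index$name)
  syn_list <- lapply(index$synonyms, function(ss) {
    tolower(vapply(ss, function(s) s$text, character(1)))
  })
  syn_flat <- data.frame(term = rep(seq_len(n), lengths(syn_list)),
                         text = unlist(syn_list) %||% character(0),
                         stringsAsFactors = FALSE)
  combined <- vapply(seq_len(n), function(i) {
    paste(c(name_lc[[i]], syn_list[[i]]), collapse = "\n")
  }, character(1))
  tok_list <- strsplit(combined, "[\n ]+")
  tok_flat <- data.frame(term = rep(seq_len(n), lengths(tok_list)),
                         tok = unlist(tok_list), stringsAsFactors = FALSE)
  list(
    search = function(query, limit = 20L) {
      q <- tolower(trimws(query))
      hits <- rep(NA_character_, n)
      if (nzchar(q)) {
        sub_hit <- grepl(q, combined, fixed = TRUE)
        hits[sub_hit] <- "substring"
        qtok <- unique(strsplit(q, " +")[[1]])
        tidx <- Reduce(intersect, lapply(qtok, function(t) {
          unique(tok_flat$term[tok_flat$tok == t])
        }))
        hits[tidx] <- "token"
        hits[unique(syn_flat$term[syn_flat$text == q])] <- "exact_synonym"
        hits[name_lc == q] <- "exact_name"
      }
      hits[index$obsolete] <- NA_character_
      idx <- which(!is.na(hits))
      scores <- c(exact_name = 1, exact_synonym = 0.9, token = 0.7,
                  substring = 0.5)
      out <- data.frame(query = rep(query, length(idx)),
                        accession = index$accession[idx],
                        name = index$name[idx], source = index$source[idx],
                        match_type = hits[idx],
                        score = unname(scores[hits[idx]]),
                        stringsAsFactors = FALSE)
      out <- out[order(-out$score, out$accession), , drop = FALSE]
      out <- head(out, limit)
      rownames(out) <- NULL
      out
    }
  )
}

# Random queries drawn from the vocabulary of an index plus noise.
random_queries <- function(index, n, seed) {
  set.seed(seed)
  toks <- unique(unlist(strsplit(tolower(index$name), " ")))
  replicate(n, {
    kind <- sample(4, 1)
    if (kind == 1) sample(index$name, 1)                       # exact name
    else if (kind == 2) paste(sample(toks, sample(1:2, 1)), collapse = " ")
    else if (kind == 3) {
      nm <- sample(index$name, 1)
      substr(nm, 1, max(3, nchar(nm) %/% 2))                   # substring
    } else paste0("zz", paste(sample(letters, 5), collapse = "")) # noise
  })
}

# Independent root -> assay-input path counter: recursive enumeration over
# a from-scratch adjacency list.
bf_path_count <- function(st) {
  kids <- lapply(st$nodes, function(n) character(0))
  for (a in st$arcs) kids[[a$parent_id]] <- c(kids[[a$parent_id]], a$child_id)
  is_assay <- vapply(st$nodes, function(n) n$kind == "assay", logical(1))
  feeds_assay <- vapply(names(st$nodes), function(id) {
    any(is_assay[kids[[id]]])
  }, logical(1))
  count <- function(v) {
    own <- if (feeds_assay[[v]]) 1L else 0L
    below <- vapply(kids[[v]], function(w) {
      if (is_assay[[w]]) 0L else count(w)
    }, integer(1))
    own + sum(below)
  }
  count(st$root_id)
}

read_bundle_bytes <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE))
  lapply(stats::setNames(files, files), function(f) {
    readBin(file.path(dir, f), "raw", file.size(file.path(dir, f)))
  })
}
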