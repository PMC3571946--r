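## Human-readable report adapters: a study report (every item and action in
## traversal order) and a protocol report. Emitted as deterministic plain
## text or minimal HTML — content, not typesetting, is the contract.

format_terms <- function(terms) {
  if (!length(terms)) return("")
  paste0(" [", paste(vapply(terms, `[[`, character(1), "accession"),
                     collapse = ", "), "]")
}

study_report_lines <- function(inv, study) {
  lines <- c(
    sprintf("STUDY REPORT: %s", study$title),
    sprintf("Investigation: %s", inv$title),
    sprintf("Study id: %s", study$id),
    ""
  )
  order <- bfs_order(study)
  items <- setdiff(order, study$root_id)
  lines <- c(lines, sprintf("Items (%d):", length(items)))
  for (id in items) {
    n <- study$nodes[[id]]
    extra <- if (n$kind == "assay") sprintf(" (modality: %s)", n$modality) else ""
    lines <- c(lines, sprintf("  - [%s] %s%s", n$kind, n$label, extra))
    for (a in n$annotations) {
      lines <- c(lines, sprintf("      %s = %s%s", a$name, a$value,
                                format_terms(a$value_terms)))
    }
    if (n$kind == "biosource") {
      for (f in names(n$miabs)) {
        lines <- c(lines, sprintf("      miabs:%s = %s", f, n$miabs[[f]]))
      }
    }
    for (att in n$attachments) {
      lines <- c(lines, sprintf("      file: %s", att$filename))
    }
  }
  lines <- c(lines, "", sprintf("Actions (%d):", length(study$arcs)))
  arc_children <- vapply(study$arcs, function(a) a$child_id, character(1))
  for (id in order) {
    for (aid in names(study$arcs)[arc_children == id]) {
      arc <- study$arcs[[aid]]
      pa <- arc$protocol_application
      desc <- sprintf("  - %s -> %s", study$nodes[[arc$parent_id]]$label,
                      study$nodes[[arc$child_id]]$label)
      if (!is.null(pa)) {
        desc <- paste0(desc, sprintf(" | protocol: %s", pa$protocol_name))
        if (nzchar(pa$action)) desc <- paste0(desc, sprintf(" | deviation: %s", pa$action))
        if (length(pa$parameters)) {
          desc <- paste0(desc, " | ", paste(
            vapply(names(pa$parameters), function(p) {
              paste0(p, "=", pa$parameters[[p]])
            }, character(1)), collapse = ", "))
        }
      }
      lines <- c(lines, desc)
    }
  }
  lines
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

as_html_doc <- function(title, lines) {
  c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\">",
    sprintf("<title>%s</title></head><body><pre>", html_escape(title)),
    html_escape(lines), "</pre></body></html>")
}

#' Render a study report
#'
#' Lists every item (node) of the study with its kind, label, annotations
#' (with attached terms), MIABS fields and attachments, then every action
#' (arc) with protocol name, deviation text and parameters, in the
#' deterministic breadth-first traversal order.
#'
#' @param inv The investigation containing the study.
#' @param study An `xr_study` (must validate).
#' @param format `"text"` or `"html"`.
#' @return Character vector of report lines.
#' @export
export_study_report <- function(inv, study, format = c("text", "html")) {
  format <- match.arg(format)
  lines <- study_report_lines(inv, study)
  if (format == "html") as_html_doc(study$title, lines) else lines
}

#' Render a protocol report
#'
#' Name, full immutable body, and every comment verbatim.
#'
#' @param protocol An `xr_protocol`.
#' @param format `"text"` or `"html"`.
#' @return Character vector of report lines.
#' @export
export_protocol_report <- function(protocol, format = c("text", "html")) {
  format <- match.arg(format)
  stopifnot(inherits(protocol, "xr_protocol"))
  lines <- c(
    sprintf("PROTOCOL REPORT: %s", protocol$name),
    sprintf("Id: %s | creator: %s", protocol$id, protocol$owner),
    "",
    "Text:",
    paste0("  ", strsplit(protocol$text, "\n", fixed = TRUE)[[1]]),
    "",
    sprintf("Comments (%d):", length(protocol$comments))
  )
  for (cm in protocol$comments) {
    lines <- c(lines, sprintf("  - %s (%s): %s", cm$author, cm$timestamp, cm$text))
  }
  if (format == "html") as_html_doc(protocol$name, lines) else lines
}
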