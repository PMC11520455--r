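#' Render a synteny plot
#'
#' Draws the query result as stacked species tracks in guide-tree order:
#' assembled fragments as grey track segments, annotated genes as blocks
#' coloured deterministically by orthogroup ([orthogroupColor()]), and
#' synteny links between adjacent tracks as ribbons (crossing when the
#' link is inverted). Primary and co-gene fragments form the top panel;
#' secondary fragments are shown in a separate bottom panel with their
#' "(filtered)" label. In microsynteny mode gene blocks are replaced by
#' exon blocks and intron lines, showing gene structure evolution.
#'
#' Every track uses its own coordinate offset (fragments are left-aligned
#' per species), so tracks from different genomes are comparable by
#' length. Output is deterministic for fixed input and options.
#'
#' @param x a [SyntenyQuery-class].
#' @param annotations named list of [GeneAnnotation-class].
#' @param file output path ending in `.svg` or `.png`, or `NULL` to
#'   return the ggplot object only.
#' @param mode `"macro"` (gene blocks, default) or `"micro"`
#'   (exon/intron structure).
#' @param width,height device size in inches.
#' @return the ggplot object, invisibly when `file` is given.
#' @export
renderSyntenyPlot <- function(x, annotations, file = NULL,
                              mode = c("macro", "micro"),
                              width = 9, height = 6) {
  mode <- match.arg(mode)
  frags <- queryFragments(x)
  ord <- x@displayOrder
  panels <- c(top = "aligned fragments", bottom = "secondary (filtered)")

  # per-(species, panel) offset: left-align the displayed fragments
  frags$panel <- ifelse(frags$class == "secondary", "bottom", "top")
  off <- stats::aggregate(t_start ~ species + panel, data = frags, FUN = min)
  names(off)[3] <- "offset"
  frags <- merge(frags, off, by = c("species", "panel"), sort = FALSE)
  frags$x0 <- frags$t_start - frags$offset
  frags$x1 <- frags$t_end - frags$offset
  frags$y <- match(frags$species, rev(ord))

  # gene glyphs within displayed fragments
  genes <- queryGenes(x)
  glyphs <- NULL; exons <- NULL; intrs <- NULL
  if (nrow(genes)) {
    g <- genes
    key <- paste(g$species, g$panel)
    offv <- stats::setNames(off$offset, paste(off$species, off$panel))
    g$offset <- offv[key]
    g <- g[!is.na(g$offset), , drop = FALSE]
    g$x0 <- g$start - g$offset; g$x1 <- g$end - g$offset
    g$y <- match(g$species, rev(ord))
    g$fill <- ifelse(is.na(g$orthogroup), "#bbbbbb",
                     orthogroupColor(g$orthogroup))
    glyphs <- g
    if (mode == "micro") {
      ex <- list(); ins <- list()
      for (i in seq_len(nrow(g))) {
        ann <- annotations[[g$species[i]]]
        if (is.null(ann)) next
        e <- geneFeatures(ann, g$gene_id[i], "exon")
        if (length(e)) {
          ex[[length(ex) + 1L]] <- data.frame(
            x0 = GenomicRanges::start(e) - g$offset[i],
            x1 = GenomicRanges::end(e) - g$offset[i],
            y = g$y[i], fill = g$fill[i], panel = g$panel[i],
            stringsAsFactors = FALSE)
        }
        it <- intronRanges(ann, g$gene_id[i])
        if (length(it)) {
          ins[[length(ins) + 1L]] <- data.frame(
            x0 = GenomicRanges::start(it) - g$offset[i],
            x1 = GenomicRanges::end(it) - g$offset[i],
            y = g$y[i], panel = g$panel[i], stringsAsFactors = FALSE)
        }
      }
      exons <- if (length(ex)) do.call(rbind, ex) else NULL
      intrs <- if (length(ins)) do.call(rbind, ins) else NULL
    }
  }

  # link ribbons between adjacent top-panel tracks
  ribbons <- NULL
  links <- queryLinks(x)
  if (nrow(links)) {
    offTop <- stats::setNames(off$offset[off$panel == "top"],
                              off$species[off$panel == "top"])
    polys <- list()
    for (i in seq_len(nrow(links))) {
      ya <- match(links$species_a[i], rev(ord))
      yb <- match(links$species_b[i], rev(ord))
      oa <- offTop[links$species_a[i]]; ob <- offTop[links$species_b[i]]
      if (is.na(oa) || is.na(ob)) next
      a0 <- links$start_a[i] - oa; a1 <- links$end_a[i] - oa
      b0 <- links$start_b[i] - ob; b1 <- links$end_b[i] - ob
      inv <- links$orientation[i] == "inverted"
      polys[[i]] <- data.frame(
        id = i,
        xx = if (inv) c(a0, a1, b0, b1) else c(a0, a1, b1, b0),
        yy = c(ya - 0.12, ya - 0.12, yb + 0.12, yb + 0.12),
        inv = inv, panel = "top", stringsAsFactors = FALSE)
    }
    ribbons <- do.call(rbind, polys)
  }

  frags$panel <- factor(panels[frags$panel], levels = unname(panels))
  p <- ggplot2::ggplot()
  if (!is.null(ribbons)) {
    ribbons$panel <- factor(panels[ribbons$panel], levels = unname(panels))
    p <- p + ggplot2::geom_polygon(
      data = ribbons,
      ggplot2::aes(x = .data$xx, y = .data$yy, group = .data$id,
                   alpha = .data$inv),
      fill = "#7a9cc6", show.legend = FALSE) +
      ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.35, `TRUE` = 0.6))
  }
  p <- p + ggplot2::geom_segment(
    data = frags,
    ggplot2::aes(x = .data$x0, xend = .data$x1, y = .data$y,
                 yend = .data$y),
    linewidth = 2.2, colour = "grey55", lineend = "butt")
  if (!is.null(glyphs) && mode == "macro") {
    glyphs$panel <- factor(panels[glyphs$panel], levels = unname(panels))
    p <- p + ggplot2::geom_rect(
      data = glyphs,
      ggplot2::aes(xmin = .data$x0, xmax = .data$x1,
                   ymin = .data$y - 0.22, ymax = .data$y + 0.22),
      fill = glyphs$fill, colour = "grey25", linewidth = 0.2)
  }
  if (mode == "micro") {
    if (!is.null(intrs)) {
      intrs$panel <- factor(panels[intrs$panel], levels = unname(panels))
      p <- p + ggplot2::geom_segment(
        data = intrs,
        ggplot2::aes(x = .data$x0, xend = .data$x1, y = .data$y,
                     yend = .data$y),
        colour = "grey25", linewidth = 0.4)
    }
    if (!is.null(exons)) {
      exons$panel <- factor(panels[exons$panel], levels = unname(panels))
      p <- p + ggplot2::geom_rect(
        data = exons,
        ggplot2::aes(xmin = .data$x0, xmax = .data$x1,
                     ymin = .data$y - 0.22, ymax = .data$y + 0.22),
        fill = exons$fill, colour = "grey25", linewidth = 0.2)
    }
  }
  lab <- frags[frags$label != "", , drop = FALSE]
  if (nrow(lab)) {
    p <- p + ggplot2::geom_text(
      data = lab,
      ggplot2::aes(x = .data$x1, y = .data$y + 0.3, label = .data$label),
      hjust = 1, size = 2.6, colour = "grey30")
  }
  qr <- queryRegion(x)
  p <- p +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_y_continuous(
      breaks = seq_along(ord), labels = rev(ord),
      limits = c(0.5, length(ord) + 0.5)) +
    ggplot2::labs(
      x = "position within displayed fragments (bp)", y = NULL,
      title = sprintf("%s:%d-%d (%s)  gap=%g  filter=%g%%",
                      as.character(GenomeInfoDb::seqnames(qr)),
                      GenomicRanges::start(qr), GenomicRanges::end(qr),
                      qr$source, x@params$gapValue, x@params$filteringPct)) +
    ggplot2::theme_bw(base_size = 9)
  if (sum(frags$panel == panels[["top"]]) <= 1L) {
    p <- p + ggplot2::annotate("text", x = 0, y = length(ord) - 0.5,
                               hjust = 0, size = 3, colour = "grey40",
      label = "no aligned fragments retained outside the reference")
  }
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    if (ext == "svg") grDevices::svg(file, width = width, height = height)
    else if (ext == "png") grDevices::png(file, width = width * 100,
                                          height = height * 100, res = 100,
                                          type = "cairo")
    else .userError("unsupported plot format '%s' (use .svg or .png)", ext)
    print(p)
    grDevices::dev.off()
    return(invisible(p))
  }
  p
}
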