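# 5x7 bitmap font defined in source so text rendering is bit-deterministic
# and free of any system font dependency. Lowercase maps to uppercase;
# unknown characters render as a box. The "bold" face dilates glyphs by one
# pixel horizontally.

glyph <- function(...) {
  rows <- c(...)
  stopifnot(length(rows) == 7L, all(nchar(rows) == 5L))
  m <- matrix(0L, 7L, 5L)
  for (i in 1:7) m[i, ] <- as.integer(strsplit(rows[[i]], "")[[1L]] == "#")
  m
}

build_font <- function() {
  g <- list()
  g[[" "]] <- glyph(".....", ".....", ".....", ".....", ".....", ".....", ".....")
  g[["A"]] <- glyph(".###.", "#...#", "#...#", "#####", "#...#", "#...#", "#...#")
  g[["B"]] <- glyph("####.", "#...#", "#...#", "####.", "#...#", "#...#", "####.")
  g[["C"]] <- glyph(".###.", "#...#", "#....", "#....", "#....", "#...#", ".###.")
  g[["D"]] <- glyph("####.", "#...#", "#...#", "#...#", "#...#", "#...#", "####.")
  g[["E"]] <- glyph("#####", "#....", "#....", "####.", "#....", "#....", "#####")
  g[["F"]] <- glyph("#####", "#....", "#....", "####.", "#....", "#....", "#....")
  g[["G"]] <- glyph(".###.", "#...#", "#....", "#.###", "#...#", "#...#", ".###.")
  g[["H"]] <- glyph("#...#", "#...#", "#...#", "#####", "#...#", "#...#", "#...#")
  g[["I"]] <- glyph(".###.", "..#..", "..#..", "..#..", "..#..", "..#..", ".###.")
  g[["J"]] <- glyph("..###", "...#.", "...#.", "...#.", "...#.", "#..#.", ".##..")
  g[["K"]] <- glyph("#...#", "#..#.", "#.#..", "##...", "#.#..", "#..#.", "#...#")
  g[["L"]] <- glyph("#....", "#....", "#....", "#....", "#....", "#....", "#####")
  g[["M"]] <- glyph("#...#", "##.##", "#.#.#", "#.#.#", "#...#", "#...#", "#...#")
  g[["N"]] <- glyph("#...#", "##..#", "#.#.#", "#..##", "#...#", "#...#", "#...#")
  g[["O"]] <- glyph(".###.", "#...#", "#...#", "#...#", "#...#", "#...#", ".###.")
  g[["P"]] <- glyph("####.", "#...#", "#...#", "####.", "#....", "#....", "#....")
  g[["Q"]] <- glyph(".###.", "#...#", "#...#", "#...#", "#.#.#", "#..#.", ".##.#")
  g[["R"]] <- glyph("####.", "#...#", "#...#", "####.", "#.#..", "#..#.", "#...#")
  g[["S"]] <- glyph(".####", "#....", "#....", ".###.", "....#", "....#", "####.")
  g[["T"]] <- glyph("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "..#..")
  g[["U"]] <- glyph("#...#", "#...#", "#...#", "#...#", "#...#", "#...#", ".###.")
  g[["V"]] <- glyph("#...#", "#...#", "#...#", "#...#", "#...#", ".#.#.", "..#..")
  g[["W"]] <- glyph("#...#", "#...#", "#...#", "#.#.#", "#.#.#", "##.##", "#...#")
  g[["X"]] <- glyph("#...#", "#...#", ".#.#.", "..#..", ".#.#.", "#...#", "#...#")
  g[["Y"]] <- glyph("#...#", "#...#", ".#.#.", "..#..", "..#..", "..#..", "..#..")
  g[["Z"]] <- glyph("#####", "....#", "...#.", "..#..", ".#...", "#....", "#####")
  g[["0"]] <- glyph(".###.", "#...#", "#..##", "#.#.#", "##..#", "#...#", ".###.")
  g[["1"]] <- glyph("..#..", ".##..", "..#..", "..#..", "..#..", "..#..", ".###.")
  g[["2"]] <- glyph(".###.", "#...#", "....#", "...#.", "..#..", ".#...", "#####")
  g[["3"]] <- glyph(".###.", "#...#", "....#", "..##.", "....#", "#...#", ".###.")
  g[["4"]] <- glyph("...#.", "..##.", ".#.#.", "#..#.", "#####", "...#.", "...#.")
  g[["5"]] <- glyph("#####", "#....", "####.", "....#", "....#", "#...#", ".###.")
  g[["6"]] <- glyph(".###.", "#....", "#....", "####.", "#...#", "#...#", ".###.")
  g[["7"]] <- glyph("#####", "....#", "...#.", "..#..", ".#...", ".#...", ".#...")
  g[["8"]] <- glyph(".###.", "#...#", "#...#", ".###.", "#...#", "#...#", ".###.")
  g[["9"]] <- glyph(".###.", "#...#", "#...#", ".####", "....#", "....#", ".###.")
  g[["."]] <- glyph(".....", ".....", ".....", ".....", ".....", ".##..", ".##..")
  g[[","]] <- glyph(".....", ".....", ".....", ".....", ".##..", "..#..", ".#...")
  g[[":"]] <- glyph(".....", ".##..", ".##..", ".....", ".##..", ".##..", ".....")
  g[[";"]] <- glyph(".....", ".##..", ".##..", ".....", ".##..", "..#..", ".#...")
  g[["!"]] <- glyph("..#..", "..#..", "..#..", "..#..", "..#..", ".....", "..#..")
  g[["?"]] <- glyph(".###.", "#...#", "....#", "...#.", "..#..", ".....", "..#..")
  g[["-"]] <- glyph(".....", ".....", ".....", "#####", ".....", ".....", ".....")
  g[["_"]] <- glyph(".....", ".....", ".....", ".....", ".....", ".....", "#####")
  g[["+"]] <- glyph(".....", "..#..", "..#..", "#####", "..#..", "..#..", ".....")
  g[["/"]] <- glyph("....#", "....#", "...#.", "..#..", ".#...", "#....", "#....")
  g[["("]] <- glyph("...#.", "..#..", ".#...", ".#...", ".#...", "..#..", "...#.")
  g[[")"]] <- glyph(".#...", "..#..", "...#.", "...#.", "...#.", "..#..", ".#...")
  g[["["]] <- glyph(".###.", ".#...", ".#...", ".#...", ".#...", ".#...", ".###.")
  g[["]"]] <- glyph(".###.", "...#.", "...#.", "...#.", "...#.", "...#.", ".###.")
  g[["="]] <- glyph(".....", ".....", "#####", ".....", "#####", ".....", ".....")
  g[["<"]] <- glyph("...#.", "..#..", ".#...", "#....", ".#...", "..#..", "...#.")
  g[[">"]] <- glyph(".#...", "..#..", "...#.", "....#", "...#.", "..#..", ".#...")
  g[["#"]] <- glyph(".#.#.", ".#.#.", "#####", ".#.#.", "#####", ".#.#.", ".#.#.")
  g[["%"]] <- glyph("##..#", "##..#", "...#.", "..#..", ".#...", "#..##", "#..##")
  g[["'"]] <- glyph("..#..", "..#..", ".....", ".....", ".....", ".....", ".....")
  g[["\""]] <- glyph(".#.#.", ".#.#.", ".....", ".....", ".....", ".....", ".....")
  g[["*"]] <- glyph(".....", ".#.#.", "..#..", "#####", "..#..", ".#.#.", ".....")
  g[["?unknown"]] <- glyph("#####", "#...#", "#...#", "#...#", "#...#", "#...#", "#####")
  g
}

get_font <- function() {
  if (is.null(.netanim$font)) .netanim$font <- build_font()
  .netanim$font
}

# Bitmap (0/1 integer matrix, 7 rows) for one text string at glyph scale 1.
# bold dilates each glyph one pixel to the right.
text_bitmap <- function(text, bold = FALSE) {
  chars <- strsplit(toupper(text), "")[[1L]]
  if (!length(chars)) return(matrix(0L, 7L, 0L))
  font <- get_font()
  cols <- list()
  for (i in seq_along(chars)) {
    gm <- font[[chars[[i]]]]
    if (is.null(gm)) gm <- font[["?unknown"]]
    if (bold) {
      shifted <- cbind(matrix(0L, 7L, 1L), gm[, 1:4])
      gm <- pmax(gm, shifted)
    }
    cols[[length(cols) + 1L]] <- gm
    if (i < length(chars)) cols[[length(cols) + 1L]] <- matrix(0L, 7L, 1L)
  }
  do.call(cbind, cols)
}
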