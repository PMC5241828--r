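# Small image fixtures built in code.

ellipse_image <- function(width = 200, height = 150, cx = width / 2,
                          cy = height / 2, a = 70, b = 45, theta = 0,
                          inside = 1, outside = 0) {
  x <- matrix(seq_len(width), width, height)
  y <- matrix(seq_len(height), width, height, byrow = TRUE)
  dx <- x - cx; dy <- y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  m <- (u / a)^2 + (v / b)^2 <= 1
  img <- matrix(outside, width, height)
  img[m] <- inside
  list(image = img, mask = m)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
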