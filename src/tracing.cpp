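#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Connected-component labelling on a 0/1 mask.
// conn = 4 or 8. Returns integer matrix of labels (0 = background).
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerMatrix cc_label_cpp(IntegerMatrix mask, int conn) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> qr, qc;
  qr.reserve(1024); qc.reserve(1024);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = { 0, 0, -1, 1, -1, 1, -1, 1};
  int ndir = (conn == 8) ? 8 : 4;
  for (int c0 = 0; c0 < W; ++c0) {
    for (int r0 = 0; r0 < H; ++r0) {
      if (mask(r0, c0) == 0 || lab(r0, c0) != 0) continue;
      ++next;
      qr.clear(); qc.clear();
      qr.push_back(r0); qc.push_back(c0);
      lab(r0, c0) = next;
      size_t head = 0;
      while (head < qr.size()) {
        int r = qr[head], c = qc[head];
        ++head;
        for (int k = 0; k < ndir; ++k) {
          int rr = r + dr8[k], cc = c + dc8[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            qr.push_back(rr); qc.push_back(cc);
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// Trace all closed boundary loops of a 0/1 mask along the half-pixel border.
//
// Pixel (r, c) (0-based) has centre (x = c, y = r); its border edges lie on
// half-integer lines. Edges are directed so the foreground is on the left,
// where left(d) = (-dy, dx) (y increases downward, along rows).
//
// At an X-configuration corner (two diagonal foreground pixels), conn8 = true
// joins the diagonal pixels into one loop and records the anti-crossing shift
// direction (o - d, components in {-1, 0, 1}) for that vertex occurrence;
// conn8 = false (label images) separates them and records no shift.
//
// Returns a list of loops; each loop is a list with half-integer vertex
// coordinates x, y (closed ring, first vertex not repeated), integer shift
// direction vectors sx, sy, and the (row, col) 0-based index of the
// foreground pixel left of the first edge.
// [[Rcpp::export(name = ".trace_loops_cpp")]]
List trace_loops_cpp(IntegerMatrix mask, bool conn8) {
  int H = mask.nrow(), W = mask.ncol();
  int VW = W + 1, VH = H + 1;
  // presence of a directed edge starting at vertex (i, j) with dir d
  // dirs: 0 = E (+x), 1 = S (+y), 2 = W, 3 = N
  std::vector<uint8_t> present((size_t)VW * VH, 0);
  std::vector<uint8_t> used((size_t)VW * VH, 0);
  auto vid = [&](int i, int j) { return (size_t)j * VW + i; };
  auto fg = [&](int r, int c) {
    return r >= 0 && r < H && c >= 0 && c < W && mask(r, c) != 0;
  };
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0) continue;
      if (!fg(r - 1, c)) present[vid(c, r)] |= 1 << 0;          // top: E
      if (!fg(r + 1, c)) present[vid(c + 1, r + 1)] |= 1 << 2;  // bottom: W
      if (!fg(r, c - 1)) present[vid(c, r + 1)] |= 1 << 3;      // left: N
      if (!fg(r, c + 1)) present[vid(c + 1, r)] |= 1 << 1;      // right: S
    }
  }
  const int di[4] = {1, 0, -1, 0};  // E S W N steps in i (x)
  const int dj[4] = {0, 1, 0, -1};  // steps in j (y)
  // X-corner successor: conn8 keeps diagonal foreground joined,
  // conn4 wraps tightly around the single pixel.
  const int succ8[4] = {3, 0, 1, 2};  // E->N, S->E, W->S, N->W
  const int succ4[4] = {1, 2, 3, 0};  // E->S, S->W, W->N, N->E
  List loops;
  for (int j0 = 0; j0 <= H; ++j0) {
    for (int i0 = 0; i0 <= W; ++i0) {
      uint8_t pres0 = present[vid(i0, j0)];
      if (!pres0) continue;
      for (int d0 = 0; d0 < 4; ++d0) {
        if (!(pres0 & (1 << d0)) || (used[vid(i0, j0)] & (1 << d0))) continue;
        std::vector<double> xs, ys;
        std::vector<int> sxs, sys;
        int i = i0, j = j0, d = d0;
        int first_r = -1, first_c = -1;
        {  // foreground pixel left of the first edge
          switch (d0) {
            case 0: first_r = j0;     first_c = i0;     break;
            case 1: first_r = j0;     first_c = i0 - 1; break;
            case 2: first_r = j0 - 1; first_c = i0 - 1; break;
            case 3: first_r = j0 - 1; first_c = i0;     break;
          }
        }
        int guard = 4 * VW * VH + 8;
        while (guard-- > 0) {
          used[vid(i, j)] |= 1 << d;
          int wi = i + di[d], wj = j + dj[d];
          uint8_t pres = present[vid(wi, wj)];
          int o, sx = 0, sy = 0;
          int ndirs = ((pres >> 0) & 1) + ((pres >> 1) & 1) +
                      ((pres >> 2) & 1) + ((pres >> 3) & 1);
          if (ndirs >= 2 && (pres & (1 << (conn8 ? succ8[d] : succ4[d])))) {
            o = conn8 ? succ8[d] : succ4[d];
            if (ndirs >= 2 && conn8) {
              // both passes through an X corner get the off-diagonal shift
              sx = di[o] - di[d];
              sy = dj[o] - dj[d];
            }
          } else {
            o = -1;
            for (int k = 0; k < 4; ++k)
              if (pres & (1 << k)) { o = k; break; }
            if (o < 0) stop("boundary tracing: dead end (corrupt mask)");
          }
          xs.push_back(wi - 0.5);
          ys.push_back(wj - 0.5);
          sxs.push_back(sx);
          sys.push_back(sy);
          i = wi; j = wj; d = o;
          if (i == i0 && j == j0 && d == d0) break;
        }
        if (guard <= 0) stop("boundary tracing: loop failed to close");
        loops.push_back(List::create(
            _["x"] = xs, _["y"] = ys, _["sx"] = sxs, _["sy"] = sys,
            _["first_r"] = first_r, _["first_c"] = first_c));
      }
    }
  }
  return loops;
}
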