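// 26-connected component labelling of a 3D logical mask (iterative BFS).
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector label_components_26(const LogicalVector& mask,
                                  const IntegerVector& dims) {
  const int na = dims[0], ns = dims[1], nc = dims[2];
  const R_xlen_t n = (R_xlen_t)na * ns * nc;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> queue;
  int next = 0;
  for (R_xlen_t v0 = 0; v0 < n; ++v0) {
    if (!mask[v0] || lab[v0] != 0) continue;
    ++next;
    lab[v0] = next;
    queue.clear();
    queue.push_back(v0);
    while (!queue.empty()) {
      const R_xlen_t v = queue.back();
      queue.pop_back();
      const int a = v % na;
      const int s = (v / na) % ns;
      const int c = v / ((R_xlen_t)na * ns);
      for (int dc = -1; dc <= 1; ++dc) {
        const int cc = c + dc; if (cc < 0 || cc >= nc) continue;
        for (int ds = -1; ds <= 1; ++ds) {
          const int ss = s + ds; if (ss < 0 || ss >= ns) continue;
          for (int da = -1; da <= 1; ++da) {
            const int aa = a + da; if (aa < 0 || aa >= na) continue;
            const R_xlen_t u = aa + (R_xlen_t)na * (ss + (R_xlen_t)ns * cc);
            if (mask[u] && lab[u] == 0) { lab[u] = next; queue.push_back(u); }
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
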