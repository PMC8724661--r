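"""Independent quantile-regression oracle (statsmodels QuantReg).

Usage: python quantreg_oracle.py data.csv tau
The CSV holds predictor columns x1..xp and a response column y.
Prints the attained check-loss objective sum_i rho_tau(y_i - x_i'beta).
"""
import sys

import numpy as np
import pandas as pd
from statsmodels.regression.quantile_regression import QuantReg

d = pd.read_csv(sys.argv[1])
tau = float(sys.argv[2])
y = d["y"].to_numpy()
X = d.drop(columns="y").to_numpy()
res = QuantReg(y, X).fit(q=tau, max_iter=10000, p_tol=1e-12)
u = y - X @ res.params
obj = float(np.sum(u * (tau - (u < 0))))
print(f"{obj:.15g}")
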