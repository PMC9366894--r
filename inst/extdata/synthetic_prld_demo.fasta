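>synthetic_QN_rich_demo synthetic test sequence: 60-aa Q/N-rich stretch flanked by charged/hydrophobic segments (not a natural protein)
MLEKDRVLEKDAVLEKDRILEKDAVLEKDRVLEKDAVLEKDRILEKDAVLEKDRVLEKDA
QNQQNYQNQQSNQQNYQNQQGNQQNYQNQQSNQQNYQNQQGNQQNYQNQQSNQQNYQNQQ
VLEKDRILEKDAVLEKDRVLEKDAVLEKDRILEKDAVLEKDRVLEKDAVLEKDRILEKDA
>synthetic_no_prld_demo synthetic test sequence: charged/hydrophobic only (not a natural protein)
MLEKDRVLEKDAVLEKDRILEKDAVLEKDRVLEKDAVLEKDRILEKDAVLEKDRVLEKDA
VLEKDRILEKDAVLEKDRVLEKDAVLEKDRILEKDAVLEKDRVLEKDAVLEKDRILEKDA
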