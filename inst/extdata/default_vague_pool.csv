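phrase,acceptable_set
long trajet,3|23
long journey,3|23
pas le temps pour aller,1|27
refus à la maison,11|21
maladie dans la maison,2|37
rien au centre ce jour,5|6
on nous a dit de revenir,36|9
route coupée,34|20
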