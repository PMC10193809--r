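>MTALTND4 99-aa altORF peptide, sense frameshift within human mtDNA nd4
MRHNYNKLHLPTTNRPKIAHCMLFNQPHSPRSNSHSHPNPLKLHRRSHSHNRPRAYILIT
ILPSKLKLRTHSQSHHNPLSRTSNSTPTNSFLMTSSKPR
>IP_306387 172-aa OpenProt candidate, sense frameshift within nd2 (AGA/AGG read as Arg)
IFYLSRPRNKHASFYSSSNQKNKPSFHRSCHQVFPHASNRIHNPSNSYPLQQYTLRTMNH
NQYYQSMLIINNHNSYSNKTRNSPLSLLSPRGYPRHPSDIRPASSHMTKTSPHLNHMPNL
SLTKRKPSPHSLNLIHHSRQLRWIKPNPATQNLSMLLNYPHRMNNSSSTVQP
>IP_306389 259-aa OpenProt candidate, sense frameshift within cox1 (AGA/AGG read as Arg)
ICNNLLHSNTHHNRRLWQLTSSPNNRCPRYGVSPHKQHKLLTLTSLSPTPARICYSGGRS
RNRLNSLPSLSRELLPPWSLRRPNHLLLTPSRCLLYLRGHQFHHNNYQYKTPCHNPMPNA
PLRLIRPNHSSPTSPISPSPSCWHHYTTNRPQPQHHLLRPRRRRRPHSMPTPILIFRSPW
SLYSYPTRLRNNLPYCNLLLRKKRTIWMHRYGLSYDINWLPRVYRVSTPYIYSRNRRRHT
SMFHLRYHNHRYPHRRQSI
>IP_306398 35-aa OpenProt candidate, sense frameshift within nd4
MSSSKPHLSPPWLSSPDEATSQNAWTQAHTSYSTP
>IP_306403 49-aa OpenProt candidate, sense frameshift within cytb
MAESSATFTPMAPQYSLSASSYTSGEAYITDHFSTQKPETSALSSCLQL
>MS_nd4_sense 95-aa MS/MS candidate, sense frameshift within nd4
MGLSRIEGLFGQVVCGGLGMCFLVLHRAIIGMWLVCWLVGLVWGALWSGSEITWLGRRSL
GGLRGPLLGVMGWVLLYDRHVIGGSLCVVVQVEAY
>MS_cox3_antisense 73-aa MS/MS candidate, antisense to cox3
MWSLPRRLPGWPSSARMRRLRAVPRTPAHAPNNRYSVPMSLWFVENSQRSANISGGEVKW
LSEALDCKSKDRG
>MS_cox1_antisense 58-aa MS/MS candidate, antisense to cox1
IMRMTAPVKLQGVWMRMAVTTRAMWLIEEYAMSDFRSVCRRQMELVMIMPHRDSTRKG
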