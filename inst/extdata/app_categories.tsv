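app_package	category
com.google.android.apps.docs	Productivity
com.microsoft.office.outlook	Productivity
com.google.android.gm	Productivity
com.google.android.apps.photos	Photography
com.farsitel.bazaar	Photography
com.adobe.lrmobile	Photography
com.whatsapp	Communication
com.facebook.orca	Communication
com.discord	Communication
com.samsung.oneconnect	Lifestyle
com.tmobile.tuesdays	Lifestyle
com.samsung.android.spay	Lifestyle
com.google.android.apps.gearhead	Auto & Vehicles
com.toyota.oneapp	Auto & Vehicles
com.carfax.mycarfax	Auto & Vehicles
com.couchsurfing.mobile.android	Travel & Local
com.google.android.apps.maps	Travel & Local
com.ubercab	Travel & Local
com.duolingo	Education
com.wonder	Education
com.instructure.candroid	Education
com.mint	Finance
com.americanexpress.android.acctsvcs.us	Finance
com.Splitwise.SplitwiseMobile	Finance
org.videolan.vlc	Video Players & Editors
com.google.android.youtube	Video Players & Editors
com.lemon.lvoverseas	Video Players & Editors
com.snapchat.android	Social
com.facebook.katana	Social
com.zhiliaoapp.musically	Social
com.audible.application	Books & Reference
com.scribd.app.reader0	Books & Reference
fm.dreemhome.chirp	Books & Reference
net.slickdeals.android	Shopping
com.amazon.mShop.android.shopping	Shopping
com.target.ui	Shopping
com.fitindex.scale	Health & Fitness
com.myfitnesspal.android	Health & Fitness
com.sec.android.app.shealth	Health & Fitness
com.amazon.avod.thirdpartyclient	Entertainment
com.netflix.mediaclient	Entertainment
com.hulu.plus	Entertainment
com.duosecurity.duomobile	Business
com.Slack	Business
com.linkedin.android	Business
com.spotify.music	Music & Audio
com.google.android.apps.youtube.music	Music & Audio
com.soundcloud.android	Music & Audio
com.sprint.care	Tools
com.google.android.googlequicksearchbox	Tools
com.google.android.gms	Tools
com.samsung.android.game.gametools	Unknown
com.sec.android.app.clockpackage	Unknown
com.google.android.calendar	Unknown
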